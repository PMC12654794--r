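# PDB ----------------------------------------------------------------------

#' Read coarse-grained chains from a PDB file
#'
#' Expects one "CA" atom per residue; optional side-chain pseudo-atoms are
#' recognized by atom name "SC" (or "CB" as a fallback).  Multi-model
#' files yield one chain per model, in model order.
#'
#' @param path PDB file path.
#' @return A list of [cg_chain()]s (length 1 for a single-model file).
#' @export
read_pdb_chains <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resnos <- unique(at$resno)
  ca_rows <- vapply(resnos, function(rn) {
    w <- which(at$resno == rn & at$elety == "CA")
    if (!length(w)) stop("residue ", rn, " has no CA record")
    w[1L]
  }, integer(1))
  sc_rows <- vapply(resnos, function(rn) {
    w <- which(at$resno == rn & at$elety %in% c("SC", "CB"))
    if (length(w)) w[1L] else NA_integer_
  }, integer(1))
  has_sc <- all(!is.na(sc_rows))
  seq1 <- vapply(at$resid[ca_rows], aa3to1, character(1))
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    cg_chain(xyz[ca_rows, , drop = FALSE],
             sc = if (has_sc) xyz[sc_rows, , drop = FALSE] else NULL,
             sequence = seq1)
  })
}

aa3to1 <- function(code) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  v <- tab[toupper(code)]
  if (is.na(v)) "X" else unname(v)
}

aa1to3 <- function(code) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  v <- tab[toupper(code)]
  if (is.na(v)) "UNK" else unname(v)
}

#' Write coarse-grained chains as a (multi-model) PDB file
#'
#' C-alpha sites are written as "CA" atoms, side-chain centers (if
#' present) as "SC" pseudo-atoms.  Multiple chains become sequential
#' MODEL/ENDMDL blocks.  Coordinates use the standard fixed-precision
#' columns (1e-3 Angstrom).
#'
#' @param chains a [cg_chain()] or a list of them (equal lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_chains <- function(chains, path) {
  if (inherits(chains, "cg_chain")) chains <- list(chains)
  multi <- length(chains) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(chains)) {
    ch <- chains[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_len(ch$n_res)) {
      res3 <- aa1to3(ch$sequence[i])
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, res3, i, ch$ca[i, 1], ch$ca[i, 2], ch$ca[i, 3]), con)
      if (!is.null(ch$sc)) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  SC  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, res3, i, ch$sc[i, 1], ch$sc[i, 2], ch$sc[i, 3]), con)
      }
    }
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

# restraint TSV --------------------------------------------------------------

.deg <- pi / 180

#' Read a restraint table
#'
#' Tab-separated file with a header row; columns `kind`, `i_res`, `lower`,
#' `upper` are required, `i_site`, `j_res`, `j_site`, `amplitude`,
#' `sigma`, `kappa`, `m` optional (defaults: CA sites; amplitude 5 for
#' distances, 1 for theta, 5 for gamma; sigma 1; kappa 0.01; m = 3 for
#' distances, -1 for angles).  Angular boundaries are in degrees in files
#' and radians internally.
#'
#' @param path TSV path.
#' @return A [restraint_set()].
#' @export
read_restraints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("kind", "i_res", "lower", "upper")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("restraint file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$kind %in% c("dist", "theta", "gamma")))
    stop("unknown restraint kind in row(s) ",
         paste(which(!df$kind %in% c("dist", "theta", "gamma")), collapse = ", "))
  bad <- which(df$lower > df$upper)
  if (length(bad)) stop("lower > upper in row(s) ", paste(bad, collapse = ", "))
  n <- nrow(df)
  get_col <- function(name, default) {
    if (name %in% names(df)) df[[name]] else rep(default, n)
  }
  ang <- df$kind %in% c("theta", "gamma")
  lower <- ifelse(ang, df$lower * .deg, df$lower)
  upper <- ifelse(ang, df$upper * .deg, df$upper)
  amp_default <- ifelse(df$kind == "theta", 1, 5)
  out <- data.frame(
    kind = df$kind, i_res = as.integer(df$i_res),
    i_site = get_col("i_site", NA_character_),
    j_res = suppressWarnings(as.integer(get_col("j_res", NA_integer_))),
    j_site = get_col("j_site", NA_character_),
    lower = lower, upper = upper,
    amplitude = as.numeric(get_col("amplitude", NA_real_)),
    sigma = as.numeric(get_col("sigma", NA_real_)),
    kappa = as.numeric(get_col("kappa", NA_real_)),
    m = as.numeric(get_col("m", NA_real_)), stringsAsFactors = FALSE)
  isd <- out$kind == "dist"
  out$i_site[isd & (is.na(out$i_site) | out$i_site == "")] <- "CA"
  out$j_site[isd & (is.na(out$j_site) | out$j_site == "")] <- "CA"
  out$i_site[!isd] <- NA_character_
  out$j_site[!isd] <- NA_character_
  out$j_res[!isd] <- NA_integer_
  out$amplitude[is.na(out$amplitude)] <- amp_default[is.na(out$amplitude)]
  out$sigma[isd & is.na(out$sigma)] <- 1
  out$kappa[isd & is.na(out$kappa)] <- 0.01
  out$sigma[!isd] <- NA_real_
  out$kappa[!isd] <- NA_real_
  out$m[is.na(out$m)] <- ifelse(isd[is.na(out$m)], 3, -1)
  if (any(isd & is.na(out$j_res))) stop("distance restraint lacks j_res")
  restraint_set(out)
}

#' Write a restraint table
#'
#' Inverse of [read_restraints()]: angular boundaries are converted back
#' to degrees.  Numbers are formatted with full (round-trip) precision.
#'
#' @param restraints a [restraint_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  df <- as.data.frame(restraints)
  ang <- df$kind %in% c("theta", "gamma")
  df$lower[ang] <- df$lower[ang] / .deg
  df$upper[ang] <- df$upper[ang] / .deg
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "i_res" &
    names(df) != "j_res"
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.17g", df[[cn]])
  for (cn in names(df)) df[[cn]][df[[cn]] %in% c("NA", NA)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run configuration and logs -------------------------------------------------

#' Read a run-configuration file
#'
#' Declarative YAML file fully determining a run: `mode` (nve, nvt or
#' mremd), `steps`, `dt`, `friction`, `mass`, `temperature`, `seed`,
#' `averaging`, `scale_energy`, a `schedule` block (n_ave, n_exch,
#' n_snap), an optional `potential` block (see [potential_config()]),
#' `restraints` (TSV path), `structures` (PDB path of starting chains)
#' and, for mremd, a `ladder` block (`set` or `temperatures` +
#' `multiplexing`).  Schedule invariants and referenced files are
#' validated at load.
#'
#' @param path YAML path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$mode <- match.arg(cfg$mode %||% "nvt", c("nvt", "nve", "mremd"))
  sch <- cfg$schedule %||% list()
  cfg$schedule <- averaging_schedule(sch$n_ave %||% 100L,
                                     sch$n_exch %||% 10000L,
                                     sch$n_snap %||% 10000L)
  cfg$potential <- do.call(potential_config, cfg$potential %||% list())
  for (f in c("restraints", "structures")) {
    if (!is.null(cfg[[f]])) {
      p <- cfg[[f]]
      if (!file.exists(p))
        p2 <- file.path(dirname(path), p)
      else p2 <- p
      if (!file.exists(p2)) stop("referenced file does not exist: ", cfg[[f]])
      cfg[[f]] <- p2
    }
  }
  cfg$steps <- as.integer(cfg$steps %||% 10000L)
  if (cfg$mode == "mremd" && cfg$steps %% cfg$schedule$n_exch != 0L)
    stop("steps must be a multiple of n_exch in mremd mode")
  if (!is.null(cfg$ladder)) {
    cfg$ladder <- if (!is.null(cfg$ladder$set)) make_ladder(cfg$ladder$set)
    else make_ladder(unlist(cfg$ladder$temperatures),
                     cfg$ladder$multiplexing)
  }
  cfg$dt <- cfg$dt %||% 4.89
  cfg$friction <- cfg$friction %||% 0.05
  cfg$mass <- cfg$mass %||% 110
  cfg$temperature <- cfg$temperature %||% 300
  cfg$averaging <- isTRUE(cfg$averaging %||% TRUE)
  cfg$scale_energy <- isTRUE(cfg$scale_energy)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run-configuration file
#'
#' @param cfg a `run_config`-style list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  if (inherits(cfg$schedule, "averaging_schedule"))
    cfg$schedule <- unclass(cfg$schedule)
  if (inherits(cfg$potential, "potential_config"))
    cfg$potential <- unclass(cfg$potential)
  if (inherits(cfg$ladder, "ladder"))
    cfg$ladder <- list(temperatures = cfg$ladder$temperatures,
                       multiplexing = cfg$ladder$M)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write / read an energy log
#'
#' Fixed-column TSV: step, replica, e_kin, e_pot, e_restraint, e_total,
#' temperature (kcal/mol and K).
#'
#' @param log data frame (`energy_log` of a trajectory).
#' @param path TSV path.
#' @return `path` / the data frame.
#' @export
write_energy_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_log
#' @export
read_energy_log <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# deterministic polynomial hash of a serialized object (hex string);
# used for manifests
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  p <- 2147483647  # 2^31 - 1; 31*h + b stays exact in doubles
  for (b in raw) h <- (h * 31 + b) %% p
  sprintf("%08x", h)
}

#' Write a reproducibility manifest
#'
#' JSON record of the configuration hash, seeds and package version that
#' produced a set of outputs, so silent nondeterminism is detectable by
#' re-running and comparing manifests.
#'
#' @param path output JSON path.
#' @param config the run configuration (any serializable object).
#' @param seeds integer vector of seeds used.
#' @param outputs optional character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds, outputs = character(0)) {
  man <- list(
    package = "rarmd",
    version = as.character(utils::packageVersion("rarmd")),
    config_hash = config_hash(config),
    seeds = as.integer(seeds),
    outputs = outputs,
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
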