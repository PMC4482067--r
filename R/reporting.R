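#' Build a run configuration
#'
#' A `run_config` collects every input path and threshold a command-line
#' run needs, so that reports are reproducible from the config alone.
#' Unspecified entries take the package defaults; the config round-trips
#' losslessly through its YAML file form.
#'
#' @param ... named entries overriding the defaults: `input_a`, `input_b`,
#'   `format` (`auto`/`pdb`/`mmcif`), `chains` (`"auto"` or chain ids),
#'   `numbering_map` (TSV path or `NULL`), `stem_catalog` (TSV path),
#'   `upstream_helix`, `downstream_helices`, `min_atoms`, `max_cycles`,
#'   `reject_sigma`, `metric`, `threshold`, `persistence`,
#'   `reporting_floor`, `contact_cutoff`, `amplification_factor`,
#'   `min_len`, `seed`, `out_dir`, plus the `simulate` block
#'   (`n_stem`, `n_arm`, `hinge_angle`, `noise_sigma`, `motif`).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    input_a = NULL, input_b = NULL, format = "auto", chains = "auto",
    numbering_map = NULL, stem_catalog = NULL,
    upstream_helix = NULL, downstream_helices = NULL,
    min_atoms = 30, max_cycles = 5, reject_sigma = 2.0,
    metric = "per_residue_backbone_mean", threshold = NULL,
    persistence = 2, reporting_floor = 0, contact_cutoff = 5.0,
    amplification_factor = 1.5, min_len = 100, seed = 1,
    out_dir = ".",
    n_stem = 6, n_arm = 12, hinge_angle = 10, noise_sigma = 0.3,
    motif = "none")
  override <- list(...)
  if (length(override) == 1 && is.list(override[[1]]) &&
      is.null(names(override))) {
    override <- override[[1]]
  }
  # [nm] <- list(...) keeps explicit NULLs instead of dropping the entry
  for (nm in names(override)) cfg[nm] <- list(override[[nm]])
  num <- c("min_atoms", "max_cycles", "reject_sigma", "persistence",
           "reporting_floor", "contact_cutoff", "amplification_factor",
           "min_len", "seed", "n_stem", "n_arm", "hinge_angle",
           "noise_sigma")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
        is.na(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop("config entry '", nm, "' must be a single nonnegative number",
           call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @param config a `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

detection_config <- function(config) {
  list(min_atoms = config$min_atoms, max_cycles = config$max_cycles,
       reject_sigma = config$reject_sigma, metric = config$metric,
       threshold = config$threshold, persistence = config$persistence,
       reporting_floor = config$reporting_floor,
       contact_cutoff = config$contact_cutoff,
       amplification_factor = config$amplification_factor)
}

# Reports are tab-separated with a commented header naming the tool
# version and the md5 of the config that produced them, so every report
# is self-describing.  Floats use fixed 3-decimal formatting to keep
# reruns byte-identical.
write_report <- function(df, path, config) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("rnapivot"))
  writeLines(c(paste0("# rnapivot ", ver),
               paste0("# config_md5 ", config_hash(config))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

load_state_pair <- function(config) {
  for (nm in c("input_a", "input_b")) {
    if (is.null(config[[nm]])) {
      stop("config entry '", nm, "' is required", call. = FALSE)
    }
  }
  prep <- function(path) {
    m <- read_structure(path, format = config$format)
    m <- select_rrna(m, selector = config$chains,
                     min_len = config$min_len)
    if (!is.null(config$numbering_map)) {
      m <- apply_numbering(m, read_numbering_map(config$numbering_map))
    }
    m
  }
  list(a = prep(config$input_a), b = prep(config$input_b))
}

#' Global-superposition control RMSDs
#'
#' Loads the two states, superimposes them chain by chain over all paired
#' atoms, and writes `global_rmsd.tsv` (one row per chain: atom counts,
#' rejections, `rmsd_all`, `rmsd_kept`).  These global values are the
#' variation that local pivot motion must exceed to be meaningful.
#'
#' @param config a [run_config()].
#' @return the report data frame, invisibly.
#' @export
cmd_global_rmsd <- function(config) {
  st <- load_state_pair(config)
  chains <- intersect(unique(st$a$atom$chain), unique(st$b$atom$chain))
  fits <- lapply(chains, function(ch) {
    a <- subset_model(st$a, which(st$a$atom$chain == ch))
    b <- subset_model(st$b, which(st$b$atom$chain == ch))
    rp <- pair_residues(a, b, method = "by_number")
    ap <- pair_atoms(rp, a, b, min_atoms = max(3, config$min_atoms))
    refine_superposition(ap, a, b, max_cycles = config$max_cycles,
                         reject_sigma = config$reject_sigma)
  })
  names(fits) <- chains
  rep <- superposition_report(fits)
  names(rep)[1] <- "chain"
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(rep, file.path(config$out_dir, "global_rmsd.tsv"), config)
  invisible(rep)
}

#' Run pivot detection and write the pivot report
#'
#' Writes `pivots.tsv` (one row per catalog helix, mirroring the
#' pivot-location and displacement tables) and a per-helix deviation
#' profile `profile_<helix>.tsv`.
#'
#' @param config a [run_config()]; `stem_catalog` is required.
#' @return the `pivot_calls` data frame, invisibly.
#' @export
cmd_detect <- function(config) {
  if (is.null(config$stem_catalog)) {
    stop("config entry 'stem_catalog' is required", call. = FALSE)
  }
  st <- load_state_pair(config)
  stems <- read_stem_catalog(config$stem_catalog)
  calls <- detect_pivots(st$a, st$b, stems,
                         config = detection_config(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(calls, file.path(config$out_dir, "pivots.tsv"), config)
  profiles <- attr(calls, "profiles")
  for (h in names(profiles)) {
    if (is.null(profiles[[h]])) next
    write_report(profiles[[h]],
                 file.path(config$out_dir,
                           paste0("profile_", gsub("\\W", "_", h), ".tsv")),
                 config)
  }
  invisible(calls)
}

#' Run cascade analysis and write the cascade / network reports
#'
#' Writes `cascade.tsv` (per downstream helix: upstream-aligned and
#' individually aligned tip displacement plus their ratio) and
#' `network.tsv` (pivot contact + induced-motion edge list).
#'
#' @param config a [run_config()]; needs `stem_catalog`,
#'   `upstream_helix` and (optionally) `downstream_helices`.
#' @return list with `cascade` and `edges`, invisibly.
#' @export
cmd_cascade <- function(config) {
  if (is.null(config$stem_catalog) || is.null(config$upstream_helix)) {
    stop("config entries 'stem_catalog' and 'upstream_helix' are required",
         call. = FALSE)
  }
  st <- load_state_pair(config)
  stems <- read_stem_catalog(config$stem_catalog)
  up <- stems[[config$upstream_helix]]
  if (is.null(up)) {
    stop("upstream helix '", config$upstream_helix, "' not in catalog",
         call. = FALSE)
  }
  down_ids <- config$downstream_helices %||%
    setdiff(names(stems), config$upstream_helix)
  casc <- cascade_table(st$a, st$b, up, stems[down_ids],
                        config = detection_config(config))
  calls <- detect_pivots(st$a, st$b, stems,
                         config = detection_config(config))
  edges <- contact_network(calls, st$a, stems, cascade = casc,
                           cutoff = config$contact_cutoff,
                           amplification_factor = config$amplification_factor)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(casc, file.path(config$out_dir, "cascade.tsv"), config)
  write_report(edges, file.path(config$out_dir, "network.tsv"), config)
  invisible(list(cascade = casc, edges = edges))
}

#' Annotate base pairs of one structure
#'
#' Writes `base_pairs.tsv` with the geometric pair records of state A.
#'
#' @param config a [run_config()]; only `input_a` is required.
#' @return the `base_pair_records`, invisibly.
#' @export
cmd_annotate <- function(config) {
  m <- read_structure(config$input_a, format = config$format)
  m <- select_rrna(m, selector = config$chains, min_len = config$min_len)
  pairs <- annotate_pairs(m)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(pairs, file.path(config$out_dir, "base_pairs.tsv"), config)
  invisible(pairs)
}

#' Simulate a synthetic hinge pair and write it to disk
#'
#' Writes the two states as PDB files, the hinge ground truth as
#' `truth.tsv` and the auto-generated stem catalog as `stems.tsv`, so a
#' full detection run needs no external input.  The seed is echoed in the
#' truth report.
#'
#' @param config a [run_config()]; uses the `n_stem`, `n_arm`,
#'   `hinge_angle`, `noise_sigma`, `motif` and `seed` entries.
#' @return the [make_hinge_pair()] result, invisibly.
#' @export
cmd_simulate <- function(config) {
  spec <- hinge_spec(n_stem = config$n_stem, n_arm = config$n_arm,
                     hinge_angle = config$hinge_angle,
                     noise_sigma = config$noise_sigma,
                     motif_at_pivot = config$motif, seed = config$seed)
  hp <- make_hinge_pair(spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(hp$a, file.path(config$out_dir, "state_a.pdb"))
  write_structure(hp$b, file.path(config$out_dir, "state_b.pdb"))
  write_stem_catalog(list(H1 = hp$truth$stem),
                     file.path(config$out_dir, "stems.tsv"))
  tr <- hp$truth
  truth_df <- data.frame(
    field = c("seed", "pivot_residue", "theta_deg", "r_tip",
              "expected_tip_chord", "axis_point", "axis_dir"),
    value = c(config$seed, tr$pivot_residue, tr$theta,
              sprintf("%.3f", tr$r_tip),
              sprintf("%.3f", tr$expected_tip_chord),
              paste(sprintf("%.3f", tr$axis_point), collapse = ","),
              paste(sprintf("%.3f", tr$axis_dir), collapse = ",")),
    stringsAsFactors = FALSE)
  write_report(truth_df, file.path(config$out_dir, "truth.tsv"), config)
  invisible(hp)
}
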