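#' Read a flat run configuration file
#'
#' YAML key/value config covering the simulation stage. Recognized keys:
#' `D_bp2_per_s`, `dt_s`, `half_life_s`, `total_time_s`, `separations`,
#' `n_trajectories`, `seed`, `hazard_mode`, `boundary_mode`,
#' `template_length`, `engine`. Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with `params` (a [diffusion_params()]), `separations`,
#'   `n_trajectories`, `seed`, `engine`, and `geometry_args`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("D_bp2_per_s", "dt_s", "half_life_s", "total_time_s",
             "separations", "n_trajectories", "seed", "hazard_mode",
             "boundary_mode", "template_length", "engine")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  get <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  params <- diffusion_params(
    D = get("D_bp2_per_s", 800),
    dt = get("dt_s", 1e-5),
    half_life = get("half_life_s", 180),
    total_time = get("total_time_s", 1200),
    hazard_mode = get("hazard_mode", "memoryless")
  )
  list(
    params = params,
    separations = get("separations", c(82, 90, 110, 150, 200, 250, 300)),
    n_trajectories = get("n_trajectories", 1000L),
    seed = get("seed", 1L),
    engine = match.arg(get("engine", "stepping"),
                       c("stepping", "fast", "analytic")),
    geometry_args = list(
      boundary_mode = get("boundary_mode", "unbounded"),
      template_length = get("template_length", Inf)
    )
  )
}

#' Write a result table as TSV with a provenance header
#'
#' Prepends `#`-prefixed comment lines recording the package version, the
#' seed, and any further parameters, then the tab-separated table.
#' [read_result_tsv()] reads such files back (header lines ignored).
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header (optional).
#' @param params Named list of further parameters to record.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, seed = NULL, params = list()) {
  hdr <- c(
    paste0("# mcmdh ", as.character(utils::packageVersion("mcmdh"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (length(params) > 0)
      paste0("# ", names(params), ": ",
             vapply(params, function(p) paste(format(p), collapse = ","),
                    character(1)))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#"))
}

#' FASTA I/O for origin sequence sets
#'
#' Thin wrappers over Biostrings: sequences travel as named character
#' vectors in the package API.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path FASTA path.
#' @return `read_origins_fasta()`: named character vector;
#'   `write_origins_fasta()`: `path`, invisibly.
#' @export
write_origins_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_origins_fasta
#' @export
read_origins_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Read a PWM from a 4-column TSV
#'
#' One row per motif position, columns A, C, G, T. Auto-detects content: a
#' matrix with any negative entry is taken as log-odds and used verbatim;
#' an all-non-negative matrix is taken as counts and converted with
#' [build_pwm()]'s pseudocount formula.
#'
#' @param path TSV path (header `A C G T`).
#' @param pseudocount,background Used only for count matrices.
#' @return A `pwm` object.
#' @export
read_pwm_tsv <- function(path, pseudocount = 1,
                         background = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25)) {
  if (!file.exists(path)) stop("PWM file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#")
  if (!all(c("A", "C", "G", "T") %in% names(tab)))
    stop("PWM TSV needs columns A, C, G, T", call. = FALSE)
  m <- t(as.matrix(tab[, c("A", "C", "G", "T")]))
  if (any(m < 0)) {
    new_pwm(m, background)
  } else {
    # counts: apply the same pseudocounted log-odds as build_pwm
    totals <- colSums(m)
    lo <- log2(sweep(m + pseudocount * background, 2, totals + pseudocount,
                     "/") / background)
    new_pwm(lo, background, pseudocount)
  }
}

#' @rdname read_pwm_tsv
#' @param pwm A `pwm` object to write (log-odds form).
#' @export
write_pwm_tsv <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  utils::write.table(as.data.frame(t(pwm$mat)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6
#'
#' One record per hit: chrom and name are the origin id, interval is the
#' 0-based half-open motif window, score is the PWM score scaled linearly
#' to 0-1000 against the PWM maximum (clipped below at 0).
#'
#' @param hits Tibble of hits with columns `origin_id`, `start`, `strand`,
#'   `score` (e.g. [scan_both_strands()] output plus an `origin_id`).
#' @param pwm The `pwm` the hits were scored with (for width and maximum).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, pwm, path) {
  stopifnot(inherits(pwm, "pwm"),
            all(c("origin_id", "start", "strand", "score") %in% names(hits)))
  bed <- data.frame(
    chrom = hits$origin_id,
    start = as.integer(hits$start),
    end = as.integer(hits$start + pwm$width),
    name = hits$origin_id,
    score = pmax(0L, pmin(1000L,
      as.integer(round(1000 * hits$score / pwm_max_score(pwm))))),
    strand = hits$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' TSV I/O for time-courses, tracks and qPCR tables
#'
#' Time-courses: columns `time_s`, `signal`. Tracks: `step`, `position_bp`.
#' qPCR: `region`, `condition`, `ct`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_timecourse_tsv <- function(path) {
  x <- read_result_tsv(path)
  stopifnot(all(c("time_s", "signal") %in% names(x)))
  x
}

#' @rdname read_timecourse_tsv
#' @export
read_track_tsv <- function(path) {
  x <- read_result_tsv(path)
  stopifnot(all(c("step", "position_bp") %in% names(x)))
  x
}

#' @rdname read_timecourse_tsv
#' @export
read_qpcr_tsv <- function(path) {
  x <- read_result_tsv(path)
  stopifnot(all(c("region", "condition", "ct") %in% names(x)))
  x
}

#' Fold change from a long-format qPCR table
#'
#' Averages Ct per (region, condition) cell and applies
#' [ddct_fold_change()].
#'
#' @param qpcr Tibble with columns `region`, `condition`, `ct`; regions
#'   must include `target_region` and `control_region`, conditions
#'   `"galactose"` and `"glucose"`.
#' @param target_region,control_region Region labels.
#' @return Fold change.
#' @export
qpcr_fold_change <- function(qpcr, target_region = "re_replication",
                             control_region = "internal_control") {
  cell <- function(region, condition) {
    v <- qpcr$ct[qpcr$region == region & qpcr$condition == condition]
    if (length(v) == 0)
      stop("no Ct values for (", region, ", ", condition, ")", call. = FALSE)
    mean(v)
  }
  ddct_fold_change(cell(target_region, "galactose"),
                   cell(control_region, "galactose"),
                   cell(target_region, "glucose"),
                   cell(control_region, "glucose"))
}
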