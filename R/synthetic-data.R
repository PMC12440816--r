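#' Demonstration EACS-like motif
#'
#' The true extended-ARS-consensus PWM is not shipped (it belongs to an
#' external origin compendium); for demonstrations and tests the package
#' carries an arbitrary 17 bp AT-rich consensus of EACS-like length and a
#' small deterministic alignment of variants around it.
#'
#' @return `demo_consensus()`: the 17 bp consensus string.
#'   `demo_pwm()`: a [build_pwm()] log-odds matrix built from the shipped
#'   alignment (uniform background, pseudocount 1).
#' @export
demo_consensus <- function() "TTTTATGTTTAGTTTTA"

#' @rdname demo_consensus
#' @export
demo_pwm <- function() {
  # consensus plus mild variants; fixed alignment so the matrix is
  # reproducible without any RNG
  sites <- c(
    "TTTTATGTTTAGTTTTA",
    "TTTTATGTTTAGTTTTA",
    "TTTTATGTTTAGTTTTA",
    "TTTTATGTTTAGTTTTA",
    "TTTCATGTTTAGTTTTA",
    "TTTTATGTTTAGATTTA",
    "ATTTATGTTTAGTTTTA",
    "TTTTATGTTTGGTTTTA",
    "TTTTATGTCTAGTTTTA",
    "TTTTACGTTTAGTTTTT"
  )
  build_pwm(sites, pseudocount = 1)
}

dna_complement <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  paste(rev(dna_complement[strsplit(toupper(x), "", fixed = TRUE)[[1]]]),
        collapse = "")
}

#' Named template fixtures used across the assays
#'
#' Returns the recurring template configurations: the ARS1-like 10 bp
#' inner spacing (below the 82 bp simulation minimum, where DH formation
#' needs no diffusion step), symmetric high-affinity pairs at 90 bp, the
#' 90 bp variant with one site swapped for the low-affinity ARS1 B2
#' element, the 300 bp pair with four lac operators between the sites
#' (inducible roadblock), the 70-93 bp helical-phasing series, and a
#' 10-300 bp loading-distance series.
#'
#' @param name One of `"ars1_like_10bp"`, `"sym_90bp"`, `"sym_90bp_b2"`,
#'   `"sym_300bp_laco"`, `"series_70_93"`, `"series_10_300"`.
#' @return A list of class `template_fixture`: `name`, `separations` (bp),
#'   `below_simulation_minimum` (logical per separation), `geometries`
#'   (a [template_geometry()] per separation, `NULL` where below the
#'   minimum), `site_types`, `roadblock`, `description`.
#' @examples
#' make_template_fixture("sym_90bp")$separations # 90
#' @export
make_template_fixture <- function(name) {
  choices <- c("ars1_like_10bp", "sym_90bp", "sym_90bp_b2", "sym_300bp_laco",
               "series_70_93", "series_10_300")
  if (!is.character(name) || length(name) != 1L || !(name %in% choices))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; choices: ", paste(choices, collapse = ", "), call. = FALSE)
  fx <- switch(name,
    ars1_like_10bp = list(sep = 10, sites = c("high_affinity", "B2"),
      roadblock = FALSE,
      desc = "ARS1-like: 10 bp between site inner edges; one ORC at a time"),
    sym_90bp = list(sep = 90, sites = c("high_affinity", "high_affinity"),
      roadblock = FALSE,
      desc = "Inverted high-affinity ORC sites spaced 90 bp apart"),
    sym_90bp_b2 = list(sep = 90, sites = c("high_affinity", "B2"),
      roadblock = FALSE,
      desc = "90 bp pair with one site replaced by the ARS1 B2 element"),
    sym_300bp_laco = list(sep = 300,
      sites = c("high_affinity", "high_affinity"), roadblock = TRUE,
      desc = "300 bp pair with four lac operators between the sites"),
    series_70_93 = list(sep = 70:93,
      sites = c("high_affinity", "high_affinity"), roadblock = FALSE,
      desc = "Helical-phasing series: separations 70-93 bp inclusive"),
    series_10_300 = list(
      sep = c(10, 30, 50, 70, 90, 110, 150, 200, 250, 300),
      sites = c("high_affinity", "high_affinity"), roadblock = FALSE,
      desc = "Loading-distance series spanning 10-300 bp")
  )
  min_sep <- closest_loading_separation()
  below <- fx$sep < min_sep
  geoms <- lapply(seq_along(fx$sep), function(i)
    if (below[i]) NULL else template_geometry(fx$sep[i]))
  structure(
    list(name = name, separations = fx$sep,
         below_simulation_minimum = below, geometries = geoms,
         site_types = fx$sites, roadblock = fx$roadblock,
         description = fx$desc),
    class = "template_fixture"
  )
}

#' @export
print.template_fixture <- function(x, ...) {
  cat("Template fixture '", x$name, "': ", x$description, "\n", sep = "")
  cat("  separations:", paste(x$separations, collapse = ", "), "bp\n")
  if (any(x$below_simulation_minimum))
    cat("  (", sum(x$below_simulation_minimum),
        " below the 82 bp diffusion-simulation minimum)\n", sep = "")
  invisible(x)
}

#' Generate origin sequences with planted, opposed motif sites
#'
#' Emits i.i.d. background sequences (default 60% AT, yeast-like) with the
#' demonstration consensus planted in head-to-head orientation: the A-like
#' site on the + strand and, `spacing` bp downstream (center to center),
#' the B2-like site on the - strand. Strength `"weak"` introduces
#' `n_mutations` point mutations into the second site; `"absent"` omits it.
#' A ground-truth table accompanies the sequences for recovery tests.
#'
#' @param n Number of origins.
#' @param spacing Center-to-center spacing(s) in bp, recycled to `n`.
#' @param strength `"strong"`, `"weak"` or `"absent"` (second site).
#' @param n_mutations Point mutations applied to the second site when
#'   `strength = "weak"` (default 3).
#' @param length Sequence length in bp (default 400).
#' @param at_fraction Background AT fraction (default 0.6).
#' @param seed Integer seed (applied locally).
#' @return A list: `sequences` (named character vector) and `truth`
#'   (tibble: origin_id, a/b2 centers and strands, spacing, strength,
#'   n_mutations).
#' @export
gen_origin_sequences <- function(n, spacing = 90,
                                 strength = c("strong", "weak", "absent"),
                                 n_mutations = 3L, length = 400L,
                                 at_fraction = 0.6, seed = 1L) {
  strength <- match.arg(strength)
  stopifnot(n >= 1, all(spacing >= 0), length >= 1,
            at_fraction > 0, at_fraction < 1)
  consensus <- demo_consensus()
  w <- nchar(consensus)
  spacing <- rep_len(spacing, n)
  probs <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
             G = (1 - at_fraction) / 2, T = at_fraction / 2)
  seed_locally(seed)
  a_chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spacing[i]
    start1 <- floor((length - sp - w) / 2)
    start2 <- start1 + sp
    if (start1 < 0 || start2 + w > length)
      stop("spacing ", sp, " bp does not fit in a ", length, " bp sequence",
           call. = FALSE)
    bases <- sample(names(probs), length, replace = TRUE, prob = probs)
    bases[(start1 + 1):(start1 + w)] <- a_chars
    b2_center <- NA_real_
    k_mut <- 0L
    if (strength != "absent") {
      site2 <- a_chars
      if (strength == "weak") {
        k_mut <- as.integer(n_mutations)
        pos <- sample(w, k_mut)
        for (p in pos) {
          site2[p] <- sample(setdiff(c("A", "C", "G", "T"), site2[p]), 1)
        }
      }
      # opposite orientation: reverse complement of the (possibly mutated)
      # consensus occupies the second window
      site2_rc <- rev(unname(dna_complement[site2]))
      bases[(start2 + 1):(start2 + w)] <- site2_rc
      b2_center <- start2 + w / 2
    }
    seqs[i] <- paste(bases, collapse = "")
    truth[[i]] <- tibble::tibble(
      origin_id = sprintf("synthetic_origin_%03d", i),
      a_center = start1 + w / 2, a_strand = "+",
      b2_center = b2_center,
      b2_strand = if (strength == "absent") NA_character_ else "-",
      spacing = if (strength == "absent") NA_real_ else sp,
      strength = strength, n_mutations = k_mut
    )
  }
  truth <- do.call(rbind, truth)
  names(seqs) <- truth$origin_id
  list(sequences = seqs, truth = truth)
}

#' Generate a synthetic retention time-course
#'
#' `signal = amplitude * 2^(-t / half_life) * (1 + eps)` with `eps`
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`,
#' truncated at 0 -- emulating bead-retention measurements of SH loss from
#' DNA.
#'
#' @param half_life Decay half-life (any time unit; `times` must match).
#' @param times Sampling times, strictly increasing.
#' @param amplitude Signal at t = 0 (default 100).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param seed Integer seed (applied locally), or `NULL` to use the current
#'   RNG state.
#' @return A tibble with columns `time` and `signal`; the generating
#'   half-life and noise level are attached as attributes.
#' @export
gen_retention_timecourse <- function(half_life, times = c(0, 2, 4, 8, 16),
                                     amplitude = 100, noise_cv = 0.05,
                                     seed = NULL) {
  stopifnot(half_life > 0, all(diff(times) > 0), amplitude > 0, noise_cv >= 0)
  if (!is.null(seed)) seed_locally(seed)
  clean <- amplitude * 2^(-times / half_life)
  eps <- if (noise_cv > 0) stats::rnorm(length(times), 0, noise_cv) else 0
  out <- tibble::tibble(time = times, signal = pmax(0, clean * (1 + eps)))
  attr(out, "half_life") <- half_life
  attr(out, "noise_cv") <- noise_cv
  out
}

#' Generate a Brownian tracking trajectory
#'
#' Cumulative sum of Gaussian steps with variance `2 D dt` each, starting
#' at 0 -- emulating single-molecule fluorescence tracking of MCM sliding
#' on DNA.
#'
#' @param D Diffusion coefficient in bp^2/s.
#' @param dt Sampling interval in s.
#' @param n_steps Number of steps (the track has `n_steps + 1` positions).
#' @param seed Integer seed (applied locally), or `NULL`.
#' @return Numeric vector of positions in bp.
#' @export
gen_tracking_trajectory <- function(D, dt, n_steps, seed = NULL) {
  stopifnot(D >= 0, dt > 0, n_steps >= 1)
  if (!is.null(seed)) seed_locally(seed)
  c(0, cumsum(stats::rnorm(n_steps, 0, sqrt(2 * D * dt))))
}
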