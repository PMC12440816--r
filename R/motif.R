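#' Build a log-odds position weight matrix from aligned binding sites
#'
#' Per-cell score `log2((count + pseudocount * background) /
#' (n_sites + pseudocount) / background)`: the pseudocount is distributed
#' over bases in proportion to the background, so uniform count columns
#' score 0 everywhere under matching background.
#'
#' @param aligned_sites Character vector of equal-length A/C/G/T sequences.
#' @param pseudocount Total pseudocount weight per column (default 1).
#' @param background Named base frequencies (A, C, G, T), default uniform.
#' @return An object of class `pwm`: a 4 x width log2-odds matrix (rows
#'   A, C, G, T) with the background and pseudocount attached.
#' @examples
#' build_pwm(c("ACGT", "ACGT", "ACGA"))
#' @export
build_pwm <- function(aligned_sites, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(length(aligned_sites) >= 1,
            all(names(background) == c("A", "C", "G", "T")),
            abs(sum(background) - 1) < 1e-8, all(background > 0),
            pseudocount >= 0)
  sites <- toupper(aligned_sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("aligned sites have unequal lengths", call. = FALSE)
  chars <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("aligned sites must contain only A/C/G/T", call. = FALSE)
  n <- length(sites)
  counts <- vapply(seq_len(w), function(j)
    tabulate(factor(chars[, j], levels = c("A", "C", "G", "T")), 4L),
    numeric(4))
  mat <- log2((counts + pseudocount * background) / (n + pseudocount) /
              background)
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  new_pwm(mat, background, pseudocount)
}

new_pwm <- function(mat, background, pseudocount = NA_real_) {
  stopifnot(nrow(mat) == 4, ncol(mat) >= 1, all(is.finite(mat)))
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(mat = mat, width = ncol(mat), background = background,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("Log-odds PWM, width", x$width, "bp; max score",
      round(pwm_max_score(x), 2), "\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' Maximum achievable PWM score
#'
#' Sum of the per-position maxima; used to set relative score thresholds.
#' @param pwm A [build_pwm()] object.
#' @return Best possible log2-odds score.
#' @export
pwm_max_score <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  sum(apply(pwm$mat, 2, max))
}

# PWM for scoring the reverse strand against the forward sequence:
# complement rows (A<->T, C<->G) and reverse the columns.
reverse_complement_pwm <- function(pwm) {
  mat <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  new_pwm(mat, pwm$background[c("T", "G", "C", "A")], pwm$pseudocount)
}

# Score every window of seq_idx (1..4 codes, NA = ambiguous) against mat.
# Windows touching an NA score NA (skipped upstream).
score_windows <- function(mat, seq_idx) {
  w <- ncol(mat)
  n_off <- length(seq_idx) - w + 1L
  if (n_off < 1L) return(numeric(0))
  scores <- numeric(n_off)
  for (j in seq_len(w)) {
    scores <- scores + mat[cbind(seq_idx[j:(j + n_off - 1L)], j)]
  }
  scores
}

#' Scan one sequence with a PWM on both strands
#'
#' Scores every offset of the forward sequence and of its reverse
#' complement; reverse-strand hits are reported in forward-strand
#' coordinates (0-based, half-open). Windows containing ambiguity codes
#' (N etc.) are skipped with a warning, since their log-odds are undefined.
#'
#' @param pwm A [build_pwm()] object.
#' @param sequence A character string or `Biostrings::DNAString`.
#' @param min_score Drop hits scoring below this (default `-Inf`: report
#'   all windows).
#' @return A tibble of motif hits: `start` (0-based forward offset),
#'   `strand` (`"+"`/`"-"`), `score`, `center` (`start + width/2`, possibly
#'   half-integer).
#' @export
scan_both_strands <- function(pwm, sequence, min_score = -Inf) {
  stopifnot(inherits(pwm, "pwm"))
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  if (n < pwm$width)
    stop("sequence (", n, " bp) shorter than PWM width (", pwm$width, ")",
         call. = FALSE)
  idx <- match(strsplit(seq_chr, "", fixed = TRUE)[[1]],
               c("A", "C", "G", "T"))
  if (anyNA(idx))
    warning("sequence contains ", sum(is.na(idx)),
            " ambiguous base(s); overlapping windows skipped")
  fwd <- score_windows(pwm$mat, idx)
  rev_ <- score_windows(reverse_complement_pwm(pwm)$mat, idx)
  hits <- tibble::tibble(
    start = rep(seq_along(fwd) - 1L, 2L),
    strand = rep(c("+", "-"), each = length(fwd)),
    score = c(fwd, rev_)
  )
  hits <- hits[!is.na(hits$score) & hits$score >= min_score, ]
  hits$center <- hits$start + pwm$width / 2
  hits[order(hits$start, hits$strand), ]
}

spacing_classes <- c("single_orc_only", "two_orc_simultaneous",
                     "fits_single_hexamer", "fits_double_hexamer")

#' Best-A / best-opposed-B2 architecture of one origin
#'
#' Finds the best PWM match overall (the A-like/EACS site; ties broken
#' leftmost, then + strand) and the best match on the opposite strand (the
#' B2-like site), and reports their center-to-center distance and the
#' distance between the inner edges of the two motif windows.
#'
#' @param pwm A [build_pwm()] object.
#' @param sequence One origin sequence.
#' @param min_score Minimum qualifying log-odds score; default 60% of
#'   [pwm_max_score()].
#' @param origin_id Optional identifier carried into outputs.
#' @return An object of class `origin_architecture` with `a_site`,
#'   `b2_site` (`NULL` when no opposite-strand hit qualifies),
#'   `center_distance`, `inner_edge_distance` (negative when the windows
#'   overlap), `score_asymmetry` and `spacing_class`
#'   ([classify_spacing()]; `NA` without a b2 site). When no hit reaches
#'   `min_score` at all, a degenerate "no EACS" architecture is returned
#'   with `a_site = NULL`.
#' @export
origin_architecture <- function(pwm, sequence,
                                min_score = 0.6 * pwm_max_score(pwm),
                                origin_id = NA_character_) {
  hits <- scan_both_strands(pwm, sequence, min_score = min_score)
  arch <- list(origin_id = origin_id, min_score = min_score,
               a_site = NULL, b2_site = NULL,
               center_distance = NA_real_, inner_edge_distance = NA_real_,
               score_asymmetry = NA_real_, spacing_class = NA_character_)
  class(arch) <- "origin_architecture"
  if (nrow(hits) == 0L) return(arch)
  pick_best <- function(h) {
    # maximal score; ties leftmost, then + strand
    h <- h[order(-h$score, h$start, h$strand), ]
    as.list(h[1L, ])
  }
  arch$a_site <- pick_best(hits)
  opp <- hits[hits$strand != arch$a_site$strand, ]
  if (nrow(opp) > 0L) {
    arch$b2_site <- pick_best(opp)
    arch$center_distance <- abs(arch$b2_site$center - arch$a_site$center)
    w <- pwm$width
    left <- if (arch$a_site$start <= arch$b2_site$start) arch$a_site else arch$b2_site
    right <- if (arch$a_site$start <= arch$b2_site$start) arch$b2_site else arch$a_site
    arch$inner_edge_distance <- right$start - (left$start + w)
    arch$score_asymmetry <- arch$a_site$score - arch$b2_site$score
    arch$spacing_class <- classify_spacing(arch$inner_edge_distance)
  } else {
    arch$spacing_class <- "single_orc_only"
  }
  arch
}

#' @export
print.origin_architecture <- function(x, ...) {
  cat("Origin architecture",
      if (!is.na(x$origin_id)) paste0("(", x$origin_id, ")"), "\n")
  if (is.null(x$a_site)) {
    cat("  no EACS match above score", round(x$min_score, 2), "\n")
    return(invisible(x))
  }
  cat(sprintf("  A site:  center %.1f (%s), score %.2f\n",
              x$a_site$center, x$a_site$strand, x$a_site$score))
  if (is.null(x$b2_site)) {
    cat("  B2 site: none above threshold ->", x$spacing_class, "\n")
  } else {
    cat(sprintf("  B2 site: center %.1f (%s), score %.2f\n",
                x$b2_site$center, x$b2_site$strand, x$b2_site$score))
    cat(sprintf("  center distance %.1f bp, inner edges %.0f bp -> %s\n",
                x$center_distance, x$inner_edge_distance, x$spacing_class))
  }
  invisible(x)
}

#' Classify ORC-site spacing into occupancy/loading categories
#'
#' Categories by the distance between the inner edges of the two ORC sites:
#' below `simultaneous_cutoff` only one ORC can bind at a time (at 10 bp --
#' the A/B1-to-B2 distance in ARS1 -- two ORC cannot bind simultaneously,
#' while 12 bp allows both); from the cutoff up, two ORC bind
#' simultaneously; with at least `orc_overhang + sh_footprint` (41 bp) of
#' room a single MCM hexamer fits between the sites, and with twice that
#' (82 bp) a double hexamer fits.
#'
#' @param inner_edge_distance Distance in bp between the inner edges of the
#'   two sites (an `origin_architecture` may be passed instead).
#' @param simultaneous_cutoff Minimum inner-edge distance at which two ORC
#'   bind simultaneously (default 12).
#' @param orc_overhang,sh_footprint Footprint constants in bp.
#' @return One of `"single_orc_only"`, `"two_orc_simultaneous"`,
#'   `"fits_single_hexamer"`, `"fits_double_hexamer"`.
#' @examples
#' classify_spacing(10) # single_orc_only, like ARS1
#' classify_spacing(12) # two_orc_simultaneous
#' @export
classify_spacing <- function(inner_edge_distance, simultaneous_cutoff = 12,
                             orc_overhang = 6, sh_footprint = 35) {
  if (inherits(inner_edge_distance, "origin_architecture")) {
    if (is.null(inner_edge_distance$b2_site))
      stop("architecture has no b2 site; spacing is undefined", call. = FALSE)
    inner_edge_distance <- inner_edge_distance$inner_edge_distance
  }
  stopifnot(is.numeric(inner_edge_distance), length(inner_edge_distance) == 1L)
  room_single <- orc_overhang + sh_footprint
  d <- inner_edge_distance
  if (d < simultaneous_cutoff) "single_orc_only"
  else if (d >= 2 * room_single) "fits_double_hexamer"
  else if (d >= room_single) "fits_single_hexamer"
  else "two_orc_simultaneous"
}

#' Summarize spacing classes and score asymmetry over an origin set
#'
#' @param architectures List of [origin_architecture()] objects.
#' @param asymmetry_threshold Origins whose A-vs-B2 score difference is
#'   below this count as "symmetric" (default 1 log2 unit).
#' @return A list with `class_fractions` (a tibble over all four spacing
#'   classes, fractions summing to 1 over classified origins),
#'   `fraction_low_asymmetry`, and `n`.
#' @export
summarize_set <- function(architectures, asymmetry_threshold = 1) {
  stopifnot(length(architectures) >= 1)
  cls <- vapply(architectures, function(a) a$spacing_class, character(1))
  cls <- factor(cls, levels = spacing_classes)
  asym <- vapply(architectures, function(a) a$score_asymmetry, numeric(1))
  tab <- table(cls)
  list(
    class_fractions = tibble::tibble(
      spacing_class = names(tab),
      n = as.integer(tab),
      fraction = as.numeric(tab) / sum(tab)
    ),
    fraction_low_asymmetry = mean(asym[!is.na(asym)] < asymmetry_threshold),
    n = length(architectures)
  )
}

#' Scan a set of origin sequences into a per-origin architecture table
#'
#' @param pwm A [build_pwm()] object.
#' @param sequences Named character vector (or `DNAStringSet`) of origin
#'   sequences.
#' @inheritParams origin_architecture
#' @return A list with `table` (one row per origin: a/b2 centers, strands,
#'   scores, distances, spacing class) and `architectures` (the underlying
#'   objects).
#' @export
scan_origin_set <- function(pwm, sequences,
                            min_score = 0.6 * pwm_max_score(pwm)) {
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("origin_", seq_along(seqs))
  archs <- lapply(seq_along(seqs), function(i)
    origin_architecture(pwm, seqs[[i]], min_score = min_score,
                        origin_id = ids[i]))
  get <- function(a, site, field)
    if (is.null(a[[site]])) NA_real_ else a[[site]][[field]]
  get_chr <- function(a, site, field)
    if (is.null(a[[site]])) NA_character_ else a[[site]][[field]]
  tab <- tibble::tibble(
    origin_id = ids,
    a_center = vapply(archs, get, numeric(1), "a_site", "center"),
    a_strand = vapply(archs, get_chr, character(1), "a_site", "strand"),
    a_score = vapply(archs, get, numeric(1), "a_site", "score"),
    b2_center = vapply(archs, get, numeric(1), "b2_site", "center"),
    b2_strand = vapply(archs, get_chr, character(1), "b2_site", "strand"),
    b2_score = vapply(archs, get, numeric(1), "b2_site", "score"),
    center_distance_bp = vapply(archs, `[[`, numeric(1), "center_distance"),
    inner_edge_distance_bp = vapply(archs, `[[`, numeric(1),
                                    "inner_edge_distance"),
    spacing_class = vapply(archs, `[[`, character(1), "spacing_class")
  )
  list(table = tab, architectures = archs)
}
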