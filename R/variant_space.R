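#' Build the variant space of a multi-position randomization
#'
#' The variant space is the set of all `n = A_1 * ... * A_M` distinct
#' amino-acid tuples producible by randomizing `M` positions, together with
#' the sampling probability of each tuple (the product of the per-position
#' amino-acid probabilities, assuming independent randomizations) and the
#' probability `p_stp` that a clone carries at least one nonsense codon and
#' is therefore dysfunctional.  Variants are enumerated in lexicographic
#' order of their amino-acid tuples (positions read 1..M, one-letter codes
#' sorted alphabetically), so variant indices are stable and reproducible.
#'
#' Variants with equal sampling probability are grouped into classes
#' (`classes`: one row per distinct probability with its variant count);
#' the coverage computations operate on these classes rather than on the raw
#' probability vector, which is what makes inclusion-exclusion feasible for
#' spaces of hundreds of variants.
#'
#' @param schemes A single scheme (name, `randomization_scheme`, or
#'   `aa_distribution`), recycled across positions, or a list of length `M`
#'   of per-position schemes.
#' @param M Number of randomized positions (used when `schemes` is a single
#'   scheme; otherwise taken from `length(schemes)`).
#' @param wt Optional wild-type amino-acid tuple (character vector of length
#'   `M`); each entry must lie in that position's support.  Required by the
#'   Gaussian landscape model.
#' @param max_positions Safety cap on `M` (the space grows as fast as
#'   `20^M`); raise `allow_large` to exceed it.
#' @param allow_large Set `TRUE` to override `max_positions`.
#' @return An object of class `variant_space`: `M`, `n`, `per_position`
#'   (list of `aa_distribution`), `variants` (n-by-M character matrix),
#'   `p` (probability vector), `p_stp`, `classes` (data frame `p`, `count`),
#'   `wt`, `wt_index`.
#' @examples
#' vs <- build_variant_space("NNK", M = 2)
#' vs$n                      # 400
#' vs$p_stp                  # 63/1024
#' @export
build_variant_space <- function(schemes, M = NULL, wt = NULL,
                                max_positions = 4L, allow_large = FALSE) {
  as_dist <- function(s) {
    if (inherits(s, "aa_distribution")) s else amino_acid_distribution(
      if (inherits(s, "randomization_scheme")) s else build_scheme(s))
  }
  if (inherits(schemes, "aa_distribution") ||
      inherits(schemes, "randomization_scheme") ||
      (is.character(schemes) && length(schemes) == 1L)) {
    if (is.null(M)) M <- 1L
    per_position <- replicate(M, as_dist(schemes), simplify = FALSE)
  } else if (is.list(schemes)) {
    per_position <- lapply(schemes, as_dist)
    M <- length(per_position)
  } else stopf("unsupported 'schemes' argument")
  if (M < 1L) stopf("need at least one randomized position")
  if (M > max_positions && !allow_large)
    stopf("M = %d exceeds max_positions = %d (variant space grows as 20^M); pass allow_large = TRUE to override",
          M, max_positions)

  supports <- lapply(per_position, function(d) names(d$q))
  A <- vapply(supports, length, integer(1))
  n <- prod(A)

  ## lexicographic enumeration: last position varies fastest
  grid <- do.call(expand.grid, c(rev(supports),
                                 list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  variants <- as.matrix(grid[, rev(seq_len(M)), drop = FALSE])
  dimnames(variants) <- list(NULL, paste0("pos", seq_len(M)))

  exact <- all(vapply(per_position, function(d) !is.null(d$counts), logical(1)))
  if (exact) {
    denom <- prod(vapply(per_position, function(d) d$denom, numeric(1)))
    num <- rep(1, n)
    for (i in seq_len(M)) num <- num * per_position[[i]]$counts[variants[, i]]
    p <- as.numeric(num) / denom
    tab <- table(num)
    classes <- data.frame(p = as.numeric(names(tab)) / denom,
                          count = as.integer(tab))
  } else {
    p <- rep(1, n)
    for (i in seq_len(M)) p <- p * per_position[[i]]$q[variants[, i]]
    p <- as.numeric(p)
    key <- signif(p, 12)
    tab <- tapply(rep(1L, n), key, sum)
    classes <- data.frame(p = as.numeric(names(tab)),
                          count = as.integer(tab))
  }
  classes <- classes[order(classes$p, decreasing = TRUE), , drop = FALSE]
  rownames(classes) <- NULL
  p_stp <- 1 - prod(vapply(per_position, function(d) 1 - d$q_stop, numeric(1)))

  wt_index <- NULL
  if (!is.null(wt)) {
    wt <- toupper(as.character(wt))
    if (length(wt) != M) stopf("wild type must have %d amino acids", M)
    for (i in seq_len(M))
      if (!wt[i] %in% supports[[i]])
        stopf("wild-type amino acid '%s' at position %d is outside the scheme's support", wt[i], i)
    wt_index <- which(apply(variants, 1L, function(r) all(r == wt)))
    stopifnot(length(wt_index) == 1L)
  }

  out <- list(M = M, n = n, per_position = per_position, variants = variants,
              p = unname(p), p_stp = p_stp, classes = classes,
              wt = wt, wt_index = wt_index)
  class(out) <- "variant_space"
  out
}

#' Construct a variant space directly from probabilities
#'
#' Builds a minimal `variant_space` from an explicit probability vector,
#' bypassing the codon layer.  Intended for small hand-specified spaces in
#' examples, oracle tests, and method development.
#'
#' @param p Probability of each variant (positive; `sum(p) + p_stp` must
#'   equal 1 within 1e-10).
#' @param p_stp Probability of a nonsense-containing clone.
#' @param variants Optional n-by-M character matrix of amino-acid tuples
#'   (defaults to single-letter labels A, B, C, ...).
#' @param wt_index Optional index of the wild-type variant.
#' @return A `variant_space`.
#' @examples
#' toy <- manual_variant_space(c(0.5, 0.5))
#' expected_coverage(toy, L = 2)  # 0.75
#' @export
manual_variant_space <- function(p, p_stp = 0, variants = NULL, wt_index = NULL) {
  p <- as.numeric(p)
  if (any(p <= 0)) stopf("all variant probabilities must be positive")
  if (abs(sum(p) + p_stp - 1) > 1e-10)
    stopf("probabilities plus stop mass must sum to 1 (got %.12g)", sum(p) + p_stp)
  n <- length(p)
  if (is.null(variants)) {
    labs <- make.unique(rep(LETTERS, length.out = n), sep = "")
    variants <- matrix(labs[seq_len(n)], ncol = 1,
                       dimnames = list(NULL, "pos1"))
  }
  variants <- as.matrix(variants)
  key <- signif(p, 12)
  tab <- tapply(rep(1L, n), key, sum)
  classes <- data.frame(p = as.numeric(names(tab)), count = as.integer(tab))
  classes <- classes[order(classes$p, decreasing = TRUE), , drop = FALSE]
  rownames(classes) <- NULL
  out <- list(M = ncol(variants), n = n, per_position = NULL,
              variants = variants, p = p, p_stp = p_stp, classes = classes,
              wt = if (!is.null(wt_index)) variants[wt_index, ] else NULL,
              wt_index = wt_index)
  class(out) <- "variant_space"
  out
}

#' @export
print.variant_space <- function(x, ...) {
  cat(sprintf("Variant space: M = %d positions, n = %d variants, stop mass p_stp = %.6g\n",
              x$M, x$n, x$p_stp))
  cat(sprintf("  %d probability classes", nrow(x$classes)))
  if (!is.null(x$wt_index))
    cat(sprintf("; wild type %s (index %d)",
                paste(x$wt, collapse = ""), x$wt_index))
  cat("\n")
  invisible(x)
}
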