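#' The standard genetic code
#'
#' Codon-to-amino-acid table (NCBI translation table 1) as a named character
#' vector; stop codons are encoded as `"*"`.  Taken from
#' [Biostrings::GENETIC_CODE] so that alternative tables from
#' [Biostrings::getGeneticCode()] can be substituted anywhere a
#' `genetic_code` argument is accepted.
#'
#' @return Named character vector of length 64 mapping codons to one-letter
#'   amino-acid codes (`"*"` for stop).
#' @export
standard_genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

## IUPAC degenerate-base expansion, e.g. "K" -> c("G","T")
.iupac_bases <- function(sym) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!sym %in% names(map)) stopf("unknown IUPAC symbol '%s'", sym)
  strsplit(map[[sym]], "")[[1]]
}

#' Build a codon randomization scheme
#'
#' A randomization scheme is the recipe used to randomize one codon: a set of
#' codons with sampling weights.  Named degenerate codons such as `"NNN"`,
#' `"NNK"`, `"NNS"`, `"NNB"` (N = A/C/G/T, K = G/T, S = C/G, B = C/G/T)
#' expand to their equal-weight codon sets; any three-letter IUPAC degenerate
#' codon is accepted.  The special name `"uniform20"` denotes the idealized
#' scheme that yields each of the twenty amino acids with probability 1/20
#' and no stop codons (achievable in practice with trinucleotide synthesis or
#' weighted primer mixtures).  Explicit codon mixtures are given as a data
#' frame with columns `codon` and `weight`.
#'
#' @param spec A scheme name (single string) or a data frame with columns
#'   `codon` (strings over A/C/G/T) and `weight` (nonnegative, summing to 1).
#' @param genetic_code Codon translation table; defaults to the standard code.
#' @return An object of class `randomization_scheme` with elements `name`,
#'   `codons`, `weights`, `equal_weight` and `genetic_code`.
#' @examples
#' build_scheme("NNK")   # 32 equal-weight codons
#' build_scheme(data.frame(codon = c("GCT", "TAA"), weight = c(0.5, 0.5)))
#' @export
build_scheme <- function(spec, genetic_code = standard_genetic_code()) {
  if (is.character(spec) && length(spec) == 1L) {
    if (identical(tolower(spec), "uniform20")) {
      out <- list(name = "uniform20", codons = character(0),
                  weights = numeric(0), equal_weight = TRUE,
                  genetic_code = genetic_code)
      class(out) <- "randomization_scheme"
      return(out)
    }
    spec <- toupper(spec)
    if (nchar(spec) != 3L) stopf("scheme name '%s' is not a 3-letter degenerate codon", spec)
    bases <- lapply(strsplit(spec, "")[[1]], .iupac_bases)
    codons <- as.matrix(expand.grid(bases[[3]], bases[[2]], bases[[1]],
                                    stringsAsFactors = FALSE))
    codons <- sort(paste0(codons[, 3], codons[, 2], codons[, 1]))
    out <- list(name = spec, codons = codons,
                weights = rep(1 / length(codons), length(codons)),
                equal_weight = TRUE, genetic_code = genetic_code)
    class(out) <- "randomization_scheme"
    return(out)
  }
  if (is.data.frame(spec)) {
    if (!all(c("codon", "weight") %in% names(spec)))
      stopf("explicit codon spec needs columns 'codon' and 'weight'")
    codons <- toupper(as.character(spec$codon))
    weights <- as.numeric(spec$weight)
    if (length(codons) == 0L) stopf("empty codon list")
    if (any(nchar(codons) != 3L) || any(!grepl("^[ACGT]{3}$", codons)))
      stopf("codons must be length-3 strings over A/C/G/T")
    if (anyDuplicated(codons)) stopf("duplicate codons in explicit scheme")
    if (any(weights < 0)) stopf("negative codon weights")
    s <- sum(weights)
    if (abs(s - 1) > 1e-9) stopf("codon weights sum to %.6g, expected 1", s)
    weights <- weights / s
    out <- list(name = "custom", codons = codons, weights = weights,
                equal_weight = length(unique(weights)) == 1L,
                genetic_code = genetic_code)
    class(out) <- "randomization_scheme"
    return(out)
  }
  stopf("unsupported scheme specification of class '%s'", class(spec)[1])
}

#' @export
print.randomization_scheme <- function(x, ...) {
  cat(sprintf("Randomization scheme '%s': %d codons%s\n", x$name,
              length(x$codons),
              if (x$equal_weight) " (equal weight)" else ""))
  invisible(x)
}

.AA20 <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))

#' Amino-acid distribution induced by a randomization scheme
#'
#' Translates a codon-level randomization scheme into the probability
#' `Q[a]` of obtaining each amino acid `a` at a randomized position, the
#' stop-codon probability `q_stop`, and the support size (number of amino
#' acids with positive probability).  For equal-weight codon sets the
#' probabilities are exact rationals, carried as integer codon counts over
#' the codon-set size; this keeps downstream coverage combinatorics free of
#' rounding drift.
#'
#' @param scheme A `randomization_scheme` (or a name passed to
#'   [build_scheme()]).
#' @return An object of class `aa_distribution` with elements `q` (named
#'   probability vector over the supported amino acids, alphabetical),
#'   `q_stop`, `support_size`, and, for equal-weight schemes, exact integer
#'   `counts` with denominator `denom`.
#' @examples
#' amino_acid_distribution("NNN")$q[["A"]]  # 4/64
#' amino_acid_distribution("NNK")$q_stop    # 1/32 (TAG)
#' @export
amino_acid_distribution <- function(scheme) {
  if (is.character(scheme)) scheme <- build_scheme(scheme)
  stopifnot(inherits(scheme, "randomization_scheme"))
  if (identical(scheme$name, "uniform20")) {
    q <- setNames(rep(1 / 20, 20), .AA20)
    counts <- setNames(rep(1, 20), .AA20)
    out <- list(q = q, q_stop = 0, support_size = 20L,
                counts = counts, denom = 20, scheme = scheme$name)
    class(out) <- "aa_distribution"
    return(out)
  }
  aa <- unname(scheme$genetic_code[scheme$codons])
  if (anyNA(aa)) stopf("codon(s) missing from the genetic code table")
  w <- tapply(scheme$weights, aa, sum)
  q_stop <- if ("*" %in% names(w)) unname(w[["*"]]) else 0
  q <- w[setdiff(names(w), "*")]
  q <- q[order(names(q))]
  out <- list(q = setNames(as.numeric(q), names(q)), q_stop = q_stop,
              support_size = length(q), scheme = scheme$name)
  if (scheme$equal_weight) {
    cnt <- table(aa)
    counts <- cnt[setdiff(names(cnt), "*")]
    counts <- counts[order(names(counts))]
    out$counts <- setNames(as.numeric(counts), names(counts))
    out$denom <- length(scheme$codons)
  }
  class(out) <- "aa_distribution"
  out
}

#' @export
print.aa_distribution <- function(x, ...) {
  cat(sprintf("Amino-acid distribution (%s): %d amino acids, stop probability %.6g\n",
              x$scheme %||% "custom", x$support_size, x$q_stop))
  print(data.frame(amino_acid = names(x$q), probability = unname(x$q),
                   codon_count = if (!is.null(x$counts)) unname(x$counts) else NA,
                   row.names = NULL))
  invisible(x)
}

#' Amino-acid table of a scheme as a data frame
#'
#' Convenience accessor used by the command-line interface: one row per
#' supported amino acid with its probability and (for equal-weight schemes)
#' codon count.
#'
#' @param scheme Scheme name or `randomization_scheme`.
#' @return A data frame with columns `amino_acid`, `probability`,
#'   `codon_count`.
#' @export
scheme_table <- function(scheme) {
  d <- amino_acid_distribution(scheme)
  data.frame(amino_acid = names(d$q), probability = unname(d$q),
             codon_count = if (!is.null(d$counts)) unname(d$counts) else NA_real_,
             row.names = NULL)
}
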