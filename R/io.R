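## metadata header written at the top of every CSV output (kept free of
## timestamps so identical configurations produce byte-identical files)
.csv_header <- function(seed, extra = character(0)) {
  c(sprintf("# satmut %s", as.character(packageVersion("satmut"))),
    sprintf("# seed=%s", format(seed)),
    extra)
}

.write_csv_with_header <- function(df, path, seed, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.csv_header(seed, extra), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a variant fitness table
#'
#' Draws one realization of the Gaussian random-effects landscape over a
#' variant space, exponentiates the transformed fitness values to emulate
#' raw assay measurements (so they must be log-transformed again before
#' fitting, mirroring how such data are produced), and returns a table of
#' `n_obs` distinct variants sampled without replacement, weighted by their
#' library probabilities.  This is the package's synthetic stand-in for an
#' experimental mutagenesis fitness table; it makes the estimation machinery
#' testable end to end without laboratory data.
#'
#' @param model A `novwein_model()` (the generating parameters).
#' @param wt Wild-type amino-acid tuple.
#' @param schemes Randomization scheme per position (default two NNK
#'   positions via recycling).
#' @param M Number of randomized positions.
#' @param n_obs Number of distinct variants in the table.
#' @param seed Integer seed (the table is deterministic given it).
#' @param include_wt Force the wild type into the table (its raw fitness is
#'   exactly 1 on the exponentiated scale).
#' @return Data frame with columns `variant_id`, `pos<i>_aa` (one per
#'   position), `raw_fitness`.
#' @export
simulate_fitness_table <- function(model, wt, schemes = "NNK", M = length(wt),
                                   n_obs = 200L, seed = 1L, include_wt = TRUE) {
  stopifnot(inherits(model, "landscape_model"), model$name == "novwein")
  space <- build_variant_space(schemes, M = M, wt = wt)
  if (n_obs > space$n)
    stopf("n_obs = %d exceeds the %d distinct variants of the space", n_obs, space$n)
  set.seed(seed)
  F <- as.numeric(.sample_F_matrix(space, model, 1L))
  idx <- sample.int(space$n, n_obs, prob = space$p)
  if (include_wt && !(space$wt_index %in% idx)) idx[1] <- space$wt_index
  idx <- sort(idx)
  df <- data.frame(variant_id = idx)
  for (i in seq_len(space$M))
    df[[sprintf("pos%d_aa", i)]] <- space$variants[idx, i]
  df$raw_fitness <- exp(F[idx])
  df
}

#' Read a variant fitness table from CSV
#'
#' Reads a CSV with columns `variant_id`, `pos1_aa`, ..., `raw_fitness`
#' (lines starting with `#` are metadata and are skipped), applies the
#' requested fitness transformation relative to the wild type, and returns a
#' [fitness_observations()] object ready for [fit_novwein_mle()].  If
#' `wt_raw` is not given and the table contains the wild-type variant, its
#' raw fitness is used.
#'
#' @param path CSV file path.
#' @param wt Wild-type amino-acid tuple.
#' @param transform `"log"` or `"boxcox"`.
#' @param lambda Box-Cox power (boxcox only).
#' @param wt_raw Wild-type raw fitness; default taken from the table.
#' @return A `fitness_observations`.
#' @export
read_fitness_table <- function(path, wt, transform = c("log", "boxcox"),
                               lambda = NULL, wt_raw = NULL) {
  transform <- match.arg(transform)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  pos_cols <- grep("^pos[0-9]+_aa$", names(df), value = TRUE)
  if (!length(pos_cols)) stopf("no pos<i>_aa columns found in %s", path)
  pos_cols <- pos_cols[order(as.integer(sub("^pos([0-9]+)_aa$", "\\1", pos_cols)))]
  if (!"raw_fitness" %in% names(df)) stopf("no raw_fitness column in %s", path)
  variants <- as.matrix(df[, pos_cols, drop = FALSE])
  if (is.null(wt_raw)) {
    is_wt <- apply(variants, 1L, function(r) all(r == wt))
    wt_raw <- if (any(is_wt)) df$raw_fitness[which(is_wt)[1]] else 1
  }
  fitness <- transform_fitness(df$raw_fitness, transform, lambda = lambda,
                               wt_raw = wt_raw)
  fitness_observations(variants, fitness, wt,
                       transform = list(kind = transform, lambda = lambda,
                                        wt_raw = wt_raw))
}

#' Generate plain-text fixtures
#'
#' Writes small reproducible text fixtures used in examples and tests:
#' `"obs_table"` is a synthetic variant fitness table
#' ([simulate_fitness_table()]); `"toy_space"` is an explicit tiny variant
#' space (columns `variant`, `p`, stop mass in the header) readable with
#' [read_toy_space()].
#'
#' @param kind `"obs_table"` or `"toy_space"`.
#' @param file Output CSV path.
#' @param seed Integer seed.
#' @param ... For `"obs_table"`: arguments of [simulate_fitness_table()]
#'   (`model`, `wt`, ...).  For `"toy_space"`: `p` (probability vector) and
#'   optional `p_stp`.
#' @return The path, invisibly.
#' @export
generate_fixture <- function(kind = c("obs_table", "toy_space"), file,
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  if (kind == "obs_table") {
    df <- do.call(simulate_fitness_table, c(args, list(seed = seed)))
    return(.write_csv_with_header(df, file, seed, "# kind=obs_table (synthetic)"))
  }
  p <- args$p %||% stopf("toy_space fixture needs a probability vector 'p'")
  p_stp <- args$p_stp %||% (1 - sum(p))
  space <- manual_variant_space(p, p_stp)
  df <- data.frame(variant = apply(space$variants, 1L, paste, collapse = ""),
                   p = space$p)
  .write_csv_with_header(df, file, seed,
                         c("# kind=toy_space (synthetic)",
                           sprintf("# p_stp=%.17g", p_stp)))
}

#' Read a toy variant space fixture
#'
#' @param path CSV written by [generate_fixture()] with `kind = "toy_space"`.
#' @return A `variant_space`.
#' @export
read_toy_space <- function(path) {
  hdr <- readLines(path, n = 10L)
  stp_line <- grep("^# p_stp=", hdr, value = TRUE)
  p_stp <- if (length(stp_line)) as.numeric(sub("^# p_stp=", "", stp_line[1])) else 0
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  manual_variant_space(df$p, p_stp, variants = matrix(df$variant, ncol = 1))
}

## ---- run configuration ----------------------------------------------------

.assert_field <- function(config, path) {
  x <- config
  for (nm in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(x) || is.null(x[[nm]]))
      stopf("config field '%s' is missing", path)
    x <- x[[nm]]
  }
  x
}

.model_from_config <- function(mc) {
  name <- mc$name %||% stopf("config field 'model.name' is missing")
  switch(name,
    novwein = novwein_model(mc$m, mc$var_pos, mc$var_aa, mc$var_nonadd),
    nk = nk_model(mc$N %||% 24L, mc$K %||% 6L, overlap = mc$overlap,
                  separation = mc$separation,
                  topology = mc$topology %||% "circular"),
    rmf = rmf_model(mc$nu %||% 60L, mc$eps %||% -1, mc$rho %||% 1),
    stopf("config model.name '%s' is not one of novwein/nk/rmf", name))
}

#' Read and write run configurations
#'
#' A run configuration is a plain list (YAML on disk) with fields `scheme`,
#' `positions`, optional `wt`, a `model` block (`name` plus model
#' parameters), `reps`, `seed`, and optional `L_grid` and `loss` blocks.
#' [write_run_config()] and [read_run_config()] round-trip it.
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_run_config()` returns the configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run a full screening analysis from a configuration
#'
#' End-to-end driver tying the modules together: builds the variant space
#' and landscape model from a configuration (list or YAML path), computes
#' the screening curve and the 95-percent-of-gap library size, optionally a
#' fitness-loss sample, and (when `out_dir` is given) writes `curve.csv`
#' (with `#` metadata header lines), `summary.json`, and `loss.csv`.
#' Outputs are deterministic given the configuration and seed; rerunning
#' produces byte-identical files.
#'
#' @param config Configuration list or YAML path (see [read_run_config()]).
#' @param out_dir Optional output directory (created if needed).
#' @return A list with elements `curve` (`screening_curve`), `lstar`
#'   (`lstar`), optionally `loss` and `exceedance`, and `config` (fully
#'   resolved), invisibly.
#' @export
run_screening <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  scheme <- .assert_field(config, "scheme")
  positions <- .assert_field(config, "positions")
  mc <- .assert_field(config, "model")
  model <- .model_from_config(mc)
  reps <- config$reps %||% 5000L
  seed <- config$seed %||% 1L
  space <- build_variant_space(scheme, M = positions, wt = config$wt)
  curve <- screening_curve(space, model,
                           L_grid = config$L_grid, reps = reps, seed = seed)
  lstar <- find_lstar95(curve, level = config$level %||% 0.95,
                        boot = config$boot %||% 200L, boot_seed = seed)
  out <- list(curve = curve, lstar = lstar, config = config)

  if (!is.null(config$loss)) {
    out$loss <- loss_distribution(space, model, L = config$loss$L,
                                  reps = reps, seed = seed,
                                  scale = config$loss$scale %||% "raw")
    out$exceedance <- exceedance_probabilities(
      out$loss, thresholds = config$loss$thresholds %||% c(5, 10, 20))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_csv_with_header(as.data.frame(curve),
                           file.path(out_dir, "curve.csv"), seed,
                           sprintf("# model=%s reps=%d conditioning=functional",
                                   model$name, reps))
    summary <- list(schema_version = 1L,
                    e_single = curve$e_single,
                    e_best_global = curve$e_best_global,
                    l_star_95 = lstar$l_star,
                    ci_low = lstar$ci[1], ci_high = lstar$ci[2],
                    reps = reps, seed = seed,
                    model = mc, scheme = scheme, positions = positions)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(out$loss))
      .write_csv_with_header(out$loss$samples,
                             file.path(out_dir, "loss.csv"), seed,
                             sprintf("# L=%d scale=%s", out$loss$L, out$loss$scale))
  }
  invisible(out)
}
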