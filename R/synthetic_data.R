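#' Configuration for a synthetic EST-library sampling experiment
#'
#' Describes the generative model behind EST-derived TPM tables: each tissue
#' is a fixed-size library of ESTs drawn multinomially from the tissue's
#' true transcript proportions. Skin and muscle sample the base proportions;
#' mammary samples the base proportions multiplied by per-gene fold changes
#' and renormalized. A fold of 1 is a null gene; folds at or above the
#' classifier's up threshold define true UP genes, folds at or below the
#' down threshold true DOWN genes.
#'
#' @param n_genes Number of genes in the panel.
#' @param base_proportions Either a numeric vector of length `n_genes`
#'   summing to 1, or a recipe string: `"equal"` (default) for uniform
#'   proportions, or `"dirichlet:<alpha>"` for a symmetric Dirichlet draw
#'   with concentration `alpha` (drawn once, deterministically from `seed`).
#' @param fold_changes Per-gene mammary fold multiplier, recycled to
#'   `n_genes` (default 1, all null).
#' @param library_sizes Named or positional integer vector of EST library
#'   sizes for (mammary, skin, muscle); default 34,000 each, the granularity
#'   typical of pooled UniGene tissue libraries.
#' @param seed Integer seed; together with a replicate number it fully
#'   determines the draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       base_proportions = "equal",
                       fold_changes = 1,
                       library_sizes = c(mammary = 34000, skin = 34000, muscle = 34000),
                       seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1 ||
      n_genes != trunc(n_genes)) {
    stop_enorthern("n_genes must be a positive integer", "enorthern_validation_error")
  }
  n_genes <- as.integer(n_genes)
  if (is.character(base_proportions)) {
    if (identical(base_proportions, "equal")) {
      p <- rep(1 / n_genes, n_genes)
    } else if (grepl("^dirichlet:", base_proportions)) {
      alpha <- as.numeric(sub("^dirichlet:", "", base_proportions))
      if (!is.finite(alpha) || alpha <= 0) {
        stop_enorthern("dirichlet concentration must be positive",
                       "enorthern_validation_error")
      }
      p <- withr::with_seed(replicate_seed(seed, 0L), {
        g <- stats::rgamma(n_genes, shape = alpha)
        g / sum(g)
      })
    } else {
      stop_enorthern(paste0("unknown proportions recipe: ", base_proportions),
                     "enorthern_validation_error")
    }
  } else {
    p <- as.numeric(base_proportions)
    if (length(p) != n_genes) {
      stop_enorthern("base_proportions length must equal n_genes",
                     "enorthern_validation_error")
    }
    if (any(p < 0)) {
      stop_enorthern("base_proportions must be non-negative",
                     "enorthern_validation_error")
    }
    if (abs(sum(p) - 1) > 1e-6) {
      stop_enorthern("base_proportions must sum to 1", "enorthern_validation_error")
    }
    p <- p / sum(p)
  }
  folds <- rep_len(as.numeric(fold_changes), n_genes)
  if (any(!is.finite(folds) | folds <= 0)) {
    stop_enorthern("fold_changes must be positive and finite",
                   "enorthern_validation_error")
  }
  sizes <- as.numeric(library_sizes)
  if (length(sizes) != 3 || any(sizes < 1 | sizes != trunc(sizes))) {
    stop_enorthern("library_sizes must be three positive integers",
                   "enorthern_validation_error")
  }
  sizes <- setNames(as.integer(sizes), c("mammary", "skin", "muscle"))
  structure(
    list(n_genes = n_genes, base_proportions = p, fold_changes = folds,
         library_sizes = sizes, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic per-replicate seed stream: distinct replicates of one config
# get distinct, independently reproducible seeds below 2^31.
replicate_seed <- function(seed, replicate) {
  as.integer((abs(as.numeric(seed)) * 131071 + as.numeric(replicate) * 524287) %%
               2147483629)
}

#' Simulate one EST-library sampling experiment
#'
#' Draws, for each tissue, gene-level EST counts from a multinomial at the
#' tissue's library size (so counts conserve the library size exactly), then
#' converts to integer TPM as `round(1e6 * count / library_size)`. This
#' reproduces the coarse count-quantization of real EST-profile TPM values:
#' at a 34,000-EST library every TPM is a multiple of about 29.4.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate number (default 1); each replicate uses its
#'   own deterministic seed derived from `config$seed`, so any replicate can
#'   be regenerated in isolation.
#' @return An object of class `sim_result`: a list with `table` (a
#'   [study_table()] of simulated TPMs), `counts` (gene x tissue integer
#'   matrix), and `truth` (tibble with per-gene `truth` in
#'   `UP`/`DOWN`/`NULL` and the `fold` used).
#' @examples
#' sim <- simulate_est_study(sim_config(5, fold_changes = c(8, 1, 1, 1, 1)))
#' sim$truth
#' @export
simulate_est_study <- function(config, replicate = 1) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$base_proportions
  p_ma <- p * config$fold_changes
  p_ma <- p_ma / sum(p_ma)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  counts <- withr::with_seed(replicate_seed(config$seed, replicate), {
    cbind(
      mammary = rmultinom(1, config$library_sizes[["mammary"]], p_ma)[, 1],
      skin    = rmultinom(1, config$library_sizes[["skin"]], p)[, 1],
      muscle  = rmultinom(1, config$library_sizes[["muscle"]], p)[, 1]
    )
  })
  rownames(counts) <- genes
  tpm <- counts
  for (tissue in colnames(counts)) {
    tpm[, tissue] <- as.integer(
      round_half_up(1e6 * counts[, tissue] / config$library_sizes[[tissue]], 0)
    )
  }
  truth <- ifelse(config$fold_changes >= 2, "UP",
                  ifelse(config$fold_changes <= 0.5, "DOWN", "NULL"))
  tab <- study_table(
    tibble::tibble(gene = genes, tpm_ma = tpm[, "mammary"], tpm_s = tpm[, "skin"],
                   tpm_mu = tpm[, "muscle"]),
    source_label = sprintf("simulated (seed %d, replicate %d)", config$seed, replicate)
  )
  structure(
    list(table = tab, counts = counts,
         truth = tibble::tibble(gene = genes, truth = truth,
                                fold = config$fold_changes),
         config = config, replicate = replicate),
    class = "sim_result"
  )
}

#' Confusion matrix and recovery rates for a simulated experiment
#'
#' Cross-tabulates the simulation's true labels (UP / DOWN / NULL) against
#' the classifier's statuses (UP / DOWN / NOT_DIFFERENTIAL / EXCLUDED;
#' exclusion is tracked as its own outcome, not folded into an error rate)
#' and reports per-class sensitivity (fraction of truth-class genes given
#' the matching call) and specificity (fraction of other-truth genes not
#' given that call).
#'
#' @param sim A [simulate_est_study()] result.
#' @param results The result tibble from [run_enorthern()] on `sim$table`.
#' @return An object of class `recovery_report`: list with `confusion`
#'   (truth x status contingency table) and `rates` (tibble with columns
#'   `class`, `sensitivity`, `specificity`).
#' @export
recovery_report <- function(sim, results) {
  stopifnot(inherits(sim, "sim_result"))
  if (!setequal(sim$truth$gene, results$gene) ||
      nrow(results) != nrow(sim$truth)) {
    stop_enorthern("gene sets of simulation and results do not match",
                   "enorthern_validation_error")
  }
  results <- results[match(sim$truth$gene, results$gene), ]
  truth <- factor(sim$truth$truth, levels = c("UP", "DOWN", "NULL"))
  status <- factor(results$status,
                   levels = c("UP", "DOWN", "NOT_DIFFERENTIAL", "EXCLUDED"))
  confusion <- table(truth = truth, status = status)
  match_call <- c(UP = "UP", DOWN = "DOWN", `NULL` = "NOT_DIFFERENTIAL")
  rates <- lapply(levels(truth), function(cl) {
    in_class <- truth == cl
    called <- status == match_call[[cl]]
    tibble::tibble(
      class = cl,
      n = sum(in_class),
      sensitivity = if (any(in_class)) mean(called[in_class]) else NA_real_,
      specificity = if (any(!in_class)) mean(!called[!in_class]) else NA_real_
    )
  })
  structure(list(confusion = confusion, rates = dplyr::bind_rows(rates)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report (truth x classifier status)\n\n")
  print(x$confusion)
  cat("\n")
  print(x$rates)
  invisible(x)
}

#' Monte-Carlo UP-call rates over simulation replicates
#'
#' Runs `n_replicates` independent draws of one configuration through the
#' classifier and returns, per gene, the fraction of replicates in which it
#' was called UP. Used to calibrate the classifier's sensitivity (for genes
#' with a true mammary fold) and false-positive rate (for null genes) under
#' EST-scale sampling noise.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of independent replicates.
#' @param classifier A [classifier_config()].
#' @return Tibble with columns `gene`, `truth`, `fold`, `up_rate`.
#' @export
up_rate_by_gene <- function(config, n_replicates,
                            classifier = classifier_config()) {
  stopifnot(inherits(config, "sim_config"))
  up_counts <- numeric(config$n_genes)
  labels <- NULL
  for (r in seq_len(n_replicates)) {
    sim <- simulate_est_study(config, replicate = r)
    status <- classify(sim$table$tpm_ma, sim$table$tpm_s, sim$table$tpm_mu,
                       classifier)
    up_counts <- up_counts + (status == "UP")
    if (is.null(labels)) labels <- sim$truth
  }
  tibble::tibble(gene = labels$gene, truth = labels$truth, fold = labels$fold,
                 up_rate = up_counts / n_replicates)
}
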