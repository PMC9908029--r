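#' Signed-signature cohort statistic
#'
#' For a signed gene signature, computes per gene the log fold change
#' between deceased and living patients (mean log expression in `dead`
#' minus mean in `live`) and averages it over the signature with the
#' gene's direction as sign: down-regulated genes contribute with a minus
#' sign. A positive statistic means the signature, as signed, is enriched
#' in deceased patients.
#'
#' @param cohort Tibble: `patient_id`, `status` (`"live"`/`"dead"`, both
#'   present), then gene columns of log expression.
#' @param signature Signed signature tibble with columns `gene` and
#'   `direction` in `{+1, -1}`. Genes absent from the cohort are dropped
#'   with a warning; an empty overlap is an error.
#' @return The statistic `T` (a single numeric, log units).
#' @export
signature_statistic <- function(cohort, signature) {
  prep <- prepare_cohort(cohort, signature)
  mean(prep$score[prep$dead]) - mean(prep$score[!prep$dead])
}

# reduce the cohort to one signed per-patient score: the statistic is the
# difference of group means of that score, which makes permutation cheap
prepare_cohort <- function(cohort, signature) {
  if (!all(c("gene", "direction") %in% names(signature))) {
    stop_input("`signature` needs columns `gene` and `direction`")
  }
  if (!all(signature$direction %in% c(-1, 1))) {
    stop_input("signature directions must be +1 or -1")
  }
  status <- cohort$status
  if (!all(status %in% c("live", "dead"))) {
    stop_input("`status` must be 'live' or 'dead'")
  }
  if (length(unique(status)) < 2L) {
    stop_input("both vital-status groups must be populated")
  }
  present <- signature$gene %in% names(cohort)
  if (!any(present)) {
    stop_input("no signature gene is present in the cohort")
  }
  if (!all(present)) {
    warn(sprintf("%d signature gene(s) absent from the cohort were dropped",
                 sum(!present)))
  }
  sig <- signature[present, ]
  expr <- as.matrix(cohort[, sig$gene, drop = FALSE])
  list(
    score = as.numeric(expr %*% sig$direction) / nrow(sig),
    dead = status == "dead",
    n_genes = nrow(sig)
  )
}

#' Label-flip permutation test for a signed signature
#'
#' Tests the association between a signed signature and patient survival.
#' The observed statistic is [signature_statistic()]; the null
#' distribution is obtained by randomly flipping the live/dead labels
#' (permuting the status vector, preserving group sizes) and recomputing
#' the statistic `B` times. The p-value uses the add-one correction
#' `p = (1 + #extreme) / (1 + B)`, so its floor is `1/(B+1)` and it is
#' never exactly zero.
#'
#' @inheritParams signature_statistic
#' @param B Number of permutation replicates (>= 100; default 10,000).
#' @param seed Seed for the permutations (deterministic result).
#' @param sidedness `"two_sided"` (default, `|T_b| >= |T_obs|`),
#'   `"greater"` or `"less"`.
#' @return An object of class `perm_test`: a list with `t_obs`,
#'   `null_sample` (length `B`), `B`, `p_value`, `sidedness`, `seed`,
#'   `n_live`, `n_dead`, `n_genes_used`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' cfg <- sim_config(seed = 5, cohort = cohort_config(
#'   planted_signature = tibble::tibble(gene = sprintf("gene%04d", 1:30),
#'                                      direction = rep(c(1L, -1L), 15))))
#' cohort <- simulate_cohort(cfg)
#' res <- permutation_test(cohort, cfg$cohort$planted_signature,
#'                         B = 1000, seed = 1)
#' glance(res)
#' @export
permutation_test <- function(cohort, signature, B = 10000L, seed = 0L,
                             sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  B <- as.integer(B)
  if (B < 100L) stop_input("`B` must be at least 100")
  prep <- prepare_cohort(cohort, signature)
  s <- prep$score
  n <- length(s)
  n_dead <- sum(prep$dead)
  n_live <- n - n_dead
  t_obs <- mean(s[prep$dead]) - mean(s[!prep$dead])

  # T_b depends only on the sum of scores in the permuted "dead" group:
  # T_b = sum_dead * (1/n_dead + 1/n_live) - sum(s)/n_live
  total <- sum(s)
  coef_ <- 1 / n_dead + 1 / n_live
  null_sample <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      sum(s[sample.int(n, n_dead)]) * coef_ - total / n_live
    }, numeric(1))
  })

  n_extreme <- switch(
    sidedness,
    two_sided = sum(abs(null_sample) >= abs(t_obs)),
    greater = sum(null_sample >= t_obs),
    less = sum(null_sample <= t_obs)
  )
  structure(
    list(
      t_obs = t_obs, null_sample = null_sample, B = B,
      p_value = (1 + n_extreme) / (1 + B),
      sidedness = sidedness, seed = as.integer(seed),
      n_live = n_live, n_dead = n_dead,
      n_genes_used = prep$n_genes
    ),
    class = "perm_test"
  )
}

#' @exportS3Method base::print
print.perm_test <- function(x, ...) {
  cat("Signed-signature label-flip permutation test\n")
  cat(sprintf("  T_obs = %.4f (average signed log fold change, dead - live)\n",
              x$t_obs))
  cat(sprintf("  B = %d permutations, %s p = %.3g (floor %.3g)\n",
              x$B, x$sidedness, x$p_value, 1 / (x$B + 1)))
  cat(sprintf("  groups: %d live / %d dead\n", x$n_live, x$n_dead))
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate` (`T_obs`),
#'   `p_value`, `B`, `sidedness`, `seed`; `glance()` adds the null-sample
#'   summary (`null_mean`, `null_sd`) and the group sizes.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(
    estimate = x$t_obs, p_value = x$p_value, B = x$B,
    sidedness = x$sidedness, seed = x$seed
  )
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(
    estimate = x$t_obs, p_value = x$p_value, B = x$B,
    sidedness = x$sidedness, null_mean = mean(x$null_sample),
    null_sd = stats::sd(x$null_sample),
    n_live = x$n_live, n_dead = x$n_dead
  )
}

#' Plot the permutation null with the observed statistic
#'
#' @param object A `perm_test` object.
#' @param ... Unused.
#' @return A ggplot: histogram of the permutation null sample with a
#'   vertical line at the observed statistic.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble(t_null = object$null_sample)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_null)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$t_obs, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "average signed log fold change (label-flip null)",
      y = "permutations",
      title = sprintf("T_obs = %.3f, %s p = %.3g (B = %d)",
                      object$t_obs, object$sidedness, object$p_value,
                      object$B)
    ) +
    ggplot2::theme_minimal()
}
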