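#' Aggregate trial-level choices into per-cell binomial counts
#'
#' The aggregated logistic model treats each participant x design cell
#' as a binomial observation: `k` target (correct) responses out of `n`
#' retrievals. Design cells are the crossing of whichever condition
#' columns the dataset carries (`wm_load` x `ltm_load` for E1/E2,
#' `set_size` x `pair_type` for E3). Cells a participant never saw are
#' retained with `n = 0` and excluded from the likelihood at fit time.
#'
#' @param data A `ChoiceDataset` tibble with a `response_category`
#'   column.
#' @param keys Condition columns; defaults to those present and
#'   non-missing in `data`.
#' @return A `CellCounts` tibble: `participant`, the key columns, `k`,
#'   `n`.
#' @export
aggregate_cells <- function(data, keys = NULL) {
  if (!"response_category" %in% names(data)) {
    stop("`data` needs a `response_category` column", call. = FALSE)
  }
  if (is.null(keys)) keys <- detect_keys_(data)
  if (length(keys) == 0) stop("no condition columns found", call. = FALSE)
  if (!"participant" %in% names(data)) data$participant <- 1L
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", keys)))) |>
    dplyr::summarise(k = sum(response_category == "target"),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(participant,
                    tidyr::nesting(!!!rlang::syms(keys)),
                    fill = list(k = 0L, n = 0L))
}

#' Specify the hierarchical binomial logistic model
#'
#' Fixed effects are the full factorial of the design's condition
#' factors under sum-to-zero contrasts, so that the Savage-Dickey test
#' of a coefficient at 0 tests "no effect". Designs whose observed
#' cells do not span the full factorial (E1/E2 observe 6 of the 8
#' WM-load x LTM-load cells) are reduced to a full-rank column set by
#' pivoted QR; focal hypotheses are then tested as cell-mean contrasts,
#' which do not depend on the coding. Regression coefficients get
#' Normal(0, 1) priors (Normal(0, 1.5) for the intercept), and each
#' participant gets correlated random deviations on every fixed-effect
#' column (maximal random-effects structure).
#'
#' @param cells A `CellCounts` tibble from [aggregate_cells()].
#' @param coef_sd,intercept_sd Prior SDs on the logit scale.
#' @return A `glmm_spec` list with the cell table, cell-level design
#'   matrix and prior SDs.
#' @export
glmm_spec <- function(cells, coef_sd = 1, intercept_sd = 1.5) {
  keys <- setdiff(names(cells), c("participant", "k", "n"))
  cell_table <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_total = sum(n), .groups = "drop") |>
    dplyr::filter(n_total > 0) |>
    dplyr::select(-dplyr::all_of("n_total")) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  fac <- cell_table
  for (kk in keys) fac[[kk]] <- factor(fac[[kk]])
  # single-level factors (e.g. an intercept-only layout) drop out of
  # the fixed-effects formula
  varying <- keys[vapply(keys, function(kk) nlevels(fac[[kk]]) > 1, TRUE)]
  if (length(varying) == 0) {
    x <- stats::model.matrix(~1, fac)
  } else {
    form <- stats::as.formula(paste("~", paste(varying, collapse = " * ")))
    x <- stats::model.matrix(form, fac,
                             contrasts.arg = lapply(
                               stats::setNames(varying, varying),
                               function(.) "contr.sum"))
  }
  qrx <- qr(x)
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  x <- x[, keep, drop = FALSE]
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient", call. = FALSE)
  labels <- do.call(paste, c(lapply(keys, function(kk) {
    paste0(sub("_", "", kk), cell_table[[kk]])
  }), sep = "_"))
  structure(list(keys = keys, cell_table = cell_table, cell_labels = labels,
                 X_cell = x, prior_sd = c(intercept_sd,
                                          rep(coef_sd, ncol(x) - 1))),
            class = "glmm_spec")
}

glmm_model_string_ <- function(P) {
  re_block <- if (P == 1) "
  for (s in 1:S) { b[s,1] ~ dnorm(0, tau_b) }
  sigma_b ~ dt(0, pow(2.5, -2), 3) T(0,)
  tau_b <- pow(sigma_b, -2)
" else "
  for (s in 1:S) { b[s,1:P] ~ dmnorm(zeros[1:P], Omega[1:P,1:P]) }
  Omega[1:P,1:P] ~ dwish(R[1:P,1:P], df)
"
  paste0("model {
  for (i in 1:N) {
    k[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- inprod(X[i,1:P], beta[1:P]) + inprod(X[i,1:P], b[pid[i],1:P])
  }
  for (j in 1:P) { beta[j] ~ dnorm(0, prior_prec[j]) }
", re_block, "}
")
}

#' Fit the hierarchical binomial logistic model
#'
#' Posterior sampling of the aggregated logistic mixed model by Gibbs
#' sampling (JAGS). The default sampler settings are 4 chains with
#' 2000 warmup iterations and 3000 retained draws each; convergence is
#' assessed by split-chain R-hat < 1.01 on all fixed effects and a
#' warning (not an error) is raised on failure.
#'
#' @param cells A `CellCounts` tibble.
#' @param spec A `glmm_spec`; built from `cells` if `NULL`.
#' @param chains,warmup,samples MCMC settings.
#' @param seed Integer seed (drives all chains' RNGs).
#' @param adapt JAGS adaptation iterations.
#' @return A `glmm_fit` list: `draws` (iterations x chains x
#'   coefficients), `spec`, `convergence`, `settings`.
#' @export
fit_binomial_glmm <- function(cells, spec = NULL, chains = 4,
                              warmup = 2000, samples = 3000, seed = 1L,
                              adapt = 500) {
  if (is.null(spec)) spec <- glmm_spec(cells)
  stopifnot(inherits(spec, "glmm_spec"))
  keys <- spec$keys
  used <- dplyr::filter(cells, n > 0)
  cell_key <- do.call(paste, c(spec$cell_table[keys], sep = "\r"))
  row_key <- do.call(paste, c(used[keys], sep = "\r"))
  ci <- match(row_key, cell_key)
  if (anyNA(ci)) stop("cells contain conditions absent from the spec",
                      call. = FALSE)
  pid <- as.integer(factor(used$participant))
  P <- ncol(spec$X_cell)
  dat <- list(k = used$k, n = used$n, X = spec$X_cell[ci, , drop = FALSE],
              pid = pid, N = nrow(used), S = max(pid), P = P,
              prior_prec = 1 / spec$prior_sd^2)
  if (P > 1) {
    dat$zeros <- rep(0, P); dat$R <- diag(P); dat$df <- P + 1
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed_(seed, paste0("chain", ch)))
  })
  model <- rjags::jags.model(textConnection(glmm_model_string_(P)),
                             data = dat, inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  stats::update(model, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = "beta",
                              n.iter = samples, progress.bar = "none")
  draws <- array(NA_real_, dim = c(samples, chains, P),
                 dimnames = list(NULL, NULL, paste0("beta[", seq_len(P), "]")))
  want <- if (P == 1 && !"beta[1]" %in% colnames(as.matrix(samp[[1]]))) {
    "beta"  # JAGS drops the index on scalar nodes
  } else paste0("beta[", seq_len(P), "]")
  for (ch in seq_len(chains)) {
    m <- as.matrix(samp[[ch]])
    draws[, ch, ] <- m[, want, drop = FALSE]
  }
  conv <- convergence_report(draws)
  if (!conv$pass) {
    warning("MCMC did not reach R-hat < ", conv$threshold,
            " on all parameters (max = ",
            round(max(conv$table$rhat), 4), ")", call. = FALSE)
  }
  structure(list(draws = draws, spec = spec, convergence = conv,
                 settings = list(chains = chains, warmup = warmup,
                                 samples = samples, seed = seed)),
            class = "glmm_fit")
}

#' Posterior draws of the cell means on the logit scale
#'
#' @param fit A `glmm_fit`.
#' @return Matrix (pooled draws x cells) with the spec's cell labels.
#' @export
cell_mean_draws <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  P <- dim(fit$draws)[3]
  beta <- matrix(fit$draws, ncol = P)
  out <- beta %*% t(fit$spec$X_cell)
  colnames(out) <- fit$spec$cell_labels
  out
}

#' Linear contrast of logit-scale cell means
#'
#' Computes one posterior draw of the contrast per retained MCMC draw,
#' along with the contrast's analytically induced prior SD (contrasts
#' are linear in the coefficients, whose priors are independent
#' normals), which feeds the Savage-Dickey Bayes factor.
#'
#' @param fit A `glmm_fit`.
#' @param weights Named numeric vector: names are cell labels (see
#'   `fit$spec$cell_labels`), values the contrast weights.
#' @param label Optional label for reporting.
#' @return A `contrast_draws` list: `draws`, `prior_sd`, `label`.
#' @export
contrast <- function(fit, weights, label = NULL) {
  stopifnot(inherits(fit, "glmm_fit"))
  labels <- fit$spec$cell_labels
  if (is.null(names(weights)) || !all(names(weights) %in% labels)) {
    stop("contrast weights must be named by cell labels: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  w <- stats::setNames(rep(0, length(labels)), labels)
  # duplicate cell names in a definition accumulate (a cell contrasted
  # with itself cancels to zero)
  for (i in seq_along(weights)) {
    w[names(weights)[i]] <- w[names(weights)[i]] + weights[i]
  }
  cm <- cell_mean_draws(fit)
  wx <- drop(t(fit$spec$X_cell) %*% w)
  prior_sd <- sqrt(sum(wx^2 * fit$spec$prior_sd^2))
  structure(list(draws = drop(cm %*% w), prior_sd = prior_sd,
                 label = label %||% paste(names(weights), collapse = " vs ")),
            class = "contrast_draws")
}

#' Proactive facilitation and interference contrasts at a set size
#'
#' Facilitation is the logit-scale accuracy difference `old_match -
#' new_new`; interference is `old_mismatch - new_new` (negative values
#' indicate a performance cost from the mismatching LTM trace). Both
#' are evaluated at the requested set size.
#'
#' @param fit A `glmm_fit` on a `set_size` x `pair_type` design.
#' @param set_size Set size at which to evaluate the contrasts.
#' @return List with `facilitation` and `interference`
#'   (`contrast_draws`).
#' @export
pf_pi_contrasts <- function(fit, set_size) {
  stopifnot(inherits(fit, "glmm_fit"))
  ct <- fit$spec$cell_table
  if (!all(c("set_size", "pair_type") %in% names(ct))) {
    stop("fit is not a set-size x pair-type model", call. = FALSE)
  }
  if (!set_size %in% ct$set_size) {
    stop("set size ", set_size, " is absent from the design", call. = FALSE)
  }
  lab <- function(pt) fit$spec$cell_labels[ct$set_size == set_size &
                                             ct$pair_type == pt]
  list(
    facilitation = contrast(
      fit, stats::setNames(c(1, -1), c(lab("old_match"), lab("new_new"))),
      label = sprintf("PF (old_match - new_new) at SS%d", set_size)),
    interference = contrast(
      fit, stats::setNames(c(1, -1), c(lab("old_mismatch"), lab("new_new"))),
      label = sprintf("PI (old_mismatch - new_new) at SS%d", set_size))
  )
}
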