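#' Ks-peak fitting, rate correction, and proportional WGD dating
#'
#' The distribution of block-median Ks carries one peak per polyploidy
#' event; fitting a k-component Gaussian mixture recovers the peak means
#' (the events' Ks ages). A shared event observed in two datasets (for
#' example the core-eudicot hexaploidy) lets lineage-specific rate
#' variation be corrected by proportionally aligning the shared peak, and
#' absolute dates follow by linear scaling against a calibrated event age.
#'
#' @name wgddate
NULL

#' Fit Gaussian mixture components to block-median Ks values
#'
#' Expectation-maximization with kmeans initialization from the given seed,
#' best of `n_restarts` restarts by likelihood. A standard-deviation floor
#' of `1e-4` prevents component collapse. Values outside `(0, 5]` are
#' dropped before fitting (Ks above 5 is saturation-adjacent and would
#' distort the mixture).
#'
#' @param medians Numeric vector of block-median Ks values.
#' @param k Number of components.
#' @param seed Integer seed controlling initialization.
#' @param n_restarts EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return A `ks_peak_fit` object: `components` tibble (`component`, `mu`,
#'   `sigma`, `weight`, ascending `mu`), `n_blocks`, `loglik`, `bic`,
#'   `converged`, and the fitted data.
#' @export
fit_ks_peaks <- function(medians, k, seed = 1, n_restarts = 10,
                         max_iter = 500, tol = 1e-8) {
  x <- medians[is.finite(medians) & medians > 0 & medians <= 5]
  if (length(x) < 10 * k) {
    abort(paste0("need at least ", 10 * k, " usable block medians to fit ",
                 k, " components (got ", length(x), ")"),
          class = "wgdtrace_validation_error")
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    fit <- em_gmm_once(x, k, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  comps <- tibble(component = seq_len(k), mu = best$mu[ord],
                  sigma = best$sigma[ord], weight = best$weight[ord])
  structure(list(components = comps, n_blocks = length(x),
                 loglik = best$loglik,
                 bic = -2 * best$loglik + (3 * k - 1) * log(length(x)),
                 converged = best$converged, iterations = best$iterations,
                 data = x, k = k, correction_factor = 1),
            class = "ks_peak_fit")
}

em_gmm_once <- function(x, k, max_iter, tol) {
  sigma_floor <- 1e-4
  n <- length(x)
  if (k == 1 || length(unique(x)) < k) {
    centers <- if (k == 1) mean(x) else
      quantile(x, probs = seq(0, 1, length.out = k), names = FALSE)
    assign <- apply(abs(outer(x, centers, "-")), 1, which.min)
  } else {
    km <- suppressWarnings(kmeans(x, centers = k, nstart = 1))
    centers <- as.numeric(km$centers)
    assign <- km$cluster
  }
  mu <- centers
  sigma <- vapply(seq_len(k), function(j) {
    s <- sd(x[assign == j])
    if (!is.finite(s) || s < sigma_floor) sigma_floor else s
  }, double(1))
  w <- vapply(seq_len(k), function(j) max(mean(assign == j), 1 / n), double(1))
  w <- w / sum(w)
  prev_ll <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sigma[j]),
                   double(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    resp <- dens / rowsum_d
    ll <- sum(log(rowsum_d))
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- vapply(seq_len(k), function(j) {
      s <- sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j])
      if (!is.finite(s) || s < sigma_floor) sigma_floor else s
    }, double(1))
    if (abs(ll - prev_ll) < tol * (1 + abs(ll))) {
      converged <- TRUE
      prev_ll <- ll
      break
    }
    prev_ll <- ll
  }
  list(mu = mu, sigma = sigma, weight = w, loglik = prev_ll,
       converged = converged, iterations = iter)
}

#' @export
print.ks_peak_fit <- function(x, ...) {
  cat("<ks_peak_fit> ", x$k, " component(s), ", x$n_blocks, " block medians",
      if (x$correction_factor != 1)
        paste0(", rate-corrected (factor ", signif(x$correction_factor, 4), ")"),
      "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Rate-correct a peak set by aligning a shared event
#'
#' Every component mean and standard deviation is multiplied by
#' `reference_mu / shared_event_mu`, so the peak generated by the shared
#' evolutionary event lands on the reference value; weights are unchanged.
#' Component mean ratios are invariant under the correction.
#'
#' @param peaks A `ks_peak_fit`.
#' @param shared_event_mu Fitted mean of the shared-event component in this
#'   dataset (must be positive and should be one of the fitted means).
#' @param reference_mu The same event's mean in the reference dataset.
#' @return The corrected `ks_peak_fit`.
#' @export
correct_ks <- function(peaks, shared_event_mu, reference_mu) {
  stopifnot(inherits(peaks, "ks_peak_fit"))
  if (!is.numeric(shared_event_mu) || shared_event_mu <= 0) {
    abort("shared_event_mu must be positive", class = "wgdtrace_validation_error")
  }
  if (!is.numeric(reference_mu) || reference_mu <= 0) {
    abort("reference_mu must be positive", class = "wgdtrace_validation_error")
  }
  if (!any(abs(peaks$components$mu - shared_event_mu) < 1e-6)) {
    warn("shared_event_mu does not match any fitted component mean")
  }
  factor <- reference_mu / shared_event_mu
  peaks$components <- peaks$components |>
    mutate(mu = .data$mu * factor, sigma = .data$sigma * factor)
  peaks$correction_factor <- peaks$correction_factor * factor
  peaks
}

#' Date an event by proportional scaling against a calibrated event
#'
#' Linear proportional dating: `t = (ks_event / ks_calib) * t_calib` applied
#' to both calibration bounds. Doubling `ks_event` doubles both bounds.
#'
#' @param ks_event Ks peak mean(s) of the event(s) to date.
#' @param ks_calib Ks peak mean of the calibrated event (for example the
#'   core-eudicot hexaploidy).
#' @param t_calib Length-2 numeric, the calibrated age interval in Mya
#'   (low, high).
#' @param event Optional event label(s), recycled against `ks_event`.
#' @return Tibble with one row per event: `event`, `ks_event`, `ks_calib`,
#'   `t_calib_low`, `t_calib_high`, `t_low`, `t_high` (Mya). Warns when
#'   extrapolating more than 1.5x past the calibration.
#' @export
date_event <- function(ks_event, ks_calib, t_calib, event = NULL) {
  if (!is.numeric(ks_calib) || ks_calib <= 0) {
    abort("ks_calib must be positive", class = "wgdtrace_validation_error")
  }
  stopifnot(length(t_calib) == 2, t_calib[1] <= t_calib[2])
  if (any(ks_event > 1.5 * ks_calib)) {
    warn("dating extrapolates more than 1.5x past the calibrated event")
  }
  if (is.null(event)) event <- paste0("event", seq_along(ks_event))
  tibble(event = event, ks_event = ks_event, ks_calib = ks_calib,
         t_calib_low = t_calib[1], t_calib_high = t_calib[2],
         t_low = ks_event / ks_calib * t_calib[1],
         t_high = ks_event / ks_calib * t_calib[2])
}

#' Assign collinear blocks to events by mixture responsibility
#'
#' Each block is labelled with the mixture component that maximizes the
#' posterior responsibility of its median Ks; blocks whose maximum
#' responsibility falls below `threshold` (or that lack a median) are left
#' `unassigned` — this avoids coin-flip labels between overlapping peaks.
#'
#' @param blocks Block tibble carrying `median_ks` (see
#'   [block_median_ks()]).
#' @param peaks A `ks_peak_fit`.
#' @param threshold Minimum posterior responsibility (default 0.6).
#' @param labels Optional character vector of event labels, one per
#'   component in ascending-`mu` order (defaults to `peak1`, `peak2`, ...).
#' @return `blocks` with `event_label` and `responsibility` columns.
#' @export
assign_blocks_to_events <- function(blocks, peaks, threshold = 0.6,
                                    labels = NULL) {
  stopifnot(inherits(peaks, "ks_peak_fit"))
  comps <- peaks$components
  if (is.null(labels)) labels <- paste0("peak", comps$component)
  stopifnot(length(labels) == nrow(comps))
  assign_one <- function(m) {
    if (is.na(m)) return(list(label = "unassigned", resp = NA_real_))
    dens <- comps$weight * dnorm(m, comps$mu, comps$sigma)
    if (sum(dens) == 0) return(list(label = "unassigned", resp = 0))
    resp <- dens / sum(dens)
    j <- which.max(resp)
    if (resp[j] < threshold) {
      list(label = "unassigned", resp = resp[j])
    } else {
      list(label = labels[j], resp = resp[j])
    }
  }
  res <- purrr::map(blocks$median_ks, assign_one)
  blocks |>
    mutate(event_label = purrr::map_chr(res, "label"),
           responsibility = purrr::map_dbl(res, "resp"))
}
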