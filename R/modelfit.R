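# Per-residue model-free fitting: models 1-5, stepwise selection,
# Monte-Carlo uncertainties.
#
# The fitter works on a per-residue observable table (field, type, value,
# sigma).  For speed it precomputes the field- and tensor-dependent
# quantities once and evaluates rates through the same .lorentz kernel as
# spectral_density(); equality with predict_relaxation() is asserted in the
# test suite.

# Field-dependent precomputation (independent of the diffusion tensor, so
# it can be reused across tensor-optimization iterations).
#' @keywords internal
.field_precompute <- function(fields_mhz, constants,
                              temperature_k = 310.15, rex_ref_mhz = 800) {
  pre <- lapply(fields_mhz, function(f) {
    fld <- spectrometer_field(f, temperature_k, constants)
    ic <- .interaction_constants(fld, constants)
    wh <- abs(fld$omega_h); wn <- abs(fld$omega_n)
    list(field_mhz = f, d2 = ic$d2, c2 = ic$c2,
         omega = c(0, wn, wh - wn, wh, wh + wn),
         rex_scale = (f / rex_ref_mhz)^2)
  })
  names(pre) <- as.character(fields_mhz)
  list(fields = pre,
       gamma_ratio = constants$gamma_h / constants$gamma_n,
       rex_ref_mhz = rex_ref_mhz)
}

# Full precomputation for one residue: fields + tensor terms.
#' @keywords internal
.fit_precompute <- function(fields_mhz, tensor, constants,
                            nh_orientation = NULL,
                            temperature_k = 310.15, rex_ref_mhz = 800) {
  pre <- .field_precompute(fields_mhz, constants, temperature_k, rex_ref_mhz)
  pre$tensor_terms <- .tensor_terms(tensor, nh_orientation)
  pre
}

# Rates for one field given generic internal-motion parameters.
# rex800 is the exchange contribution at the reference field (0 if none).
#' @keywords internal
.fast_triple <- function(s2, amp, tau_int_s, rex800, fp, tt, gamma_ratio) {
  j <- 0
  for (k in seq_along(tt$taus)) {
    tau_k <- tt$taus[k]
    term <- s2 * .lorentz(tau_k, fp$omega)
    if (amp - s2 != 0 && tau_int_s > 0) {
      tau_p <- 1 / (1 / tau_k + 1 / tau_int_s)
      term <- term + (amp - s2) * .lorentz(tau_p, fp$omega)
    }
    j <- j + tt$weights[k] * term
  }
  j <- 0.4 * j
  r1 <- (fp$d2 / 4) * (j[3] + 3 * j[2] + 6 * j[5]) + fp$c2 * j[2]
  r2 <- (fp$d2 / 8) * (4 * j[1] + j[3] + 3 * j[2] + 6 * j[4] + 6 * j[5]) +
    (fp$c2 / 6) * (4 * j[1] + 3 * j[2]) + rex800 * fp$rex_scale
  noe <- 1 + (fp$d2 / 4) * gamma_ratio * (6 * j[5] - j[3]) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}

# theta parameterizations (natural units):
#   model 1: s2 | 2: s2, tau_e_ps | 3: s2, rex | 4: s2, tau_e_ps, rex
#   model 5: s2f, s2s, tau_s_ns
#' @keywords internal
.theta_to_motion <- function(model, theta) {
  theta <- unname(as.numeric(theta))   # keep rate names clean downstream
  switch(as.character(model),
    "1" = list(s2 = theta[1], amp = 1, tau_int_s = 0, rex = 0),
    "2" = list(s2 = theta[1], amp = 1, tau_int_s = theta[2] * 1e-12, rex = 0),
    "3" = list(s2 = theta[1], amp = 1, tau_int_s = 0, rex = theta[2]),
    "4" = list(s2 = theta[1], amp = 1, tau_int_s = theta[2] * 1e-12,
               rex = theta[3]),
    "5" = list(s2 = theta[1] * theta[2], amp = theta[1],
               tau_int_s = theta[3] * 1e-9, rex = 0))
}

#' @keywords internal
.model_npar <- c("1" = 1L, "2" = 2L, "3" = 2L, "4" = 3L, "5" = 3L)

# Observable table split into plain per-field vectors for the hot loop.
#' @keywords internal
.prep_obs <- function(obs, pre) {
  lapply(pre$fields, function(fp) {
    rows <- which(obs$field_mhz == fp$field_mhz)
    list(fp = fp,
         types = match(obs$type[rows], c("r1", "r2", "noe")),
         values = obs$value[rows], sigmas = obs$sigma[rows])
  })
}

# chi2 of one parameter vector against prepared observables.
#' @keywords internal
.residue_chi2 <- function(model, theta, pobs, pre) {
  mo <- .theta_to_motion(model, theta)
  chi2 <- 0
  for (po in pobs) {
    if (length(po$types) == 0L) next
    tr <- .fast_triple(mo$s2, mo$amp, mo$tau_int_s, mo$rex, po$fp,
                       pre$tensor_terms, pre$gamma_ratio)
    chi2 <- chi2 + sum(((po$values - tr[po$types]) / po$sigmas)^2)
  }
  # degenerate corners (e.g. S2 = 0 with tau_e = 0 -> all rates 0, NOE 0/0)
  if (!is.finite(chi2)) chi2 <- 1e12
  chi2
}

# Bounds and deterministic coarse-grid starts per model.
#' @keywords internal
.model_search_space <- function(model, tau_r_ns) {
  s2g <- seq(0.3, 1.0, by = 0.1)
  teg <- 10^seq(0, 3, length.out = 7)          # 1 ps .. 1 ns
  rxg <- c(0, 2, 5, 10)
  te_max <- min(3000, tau_r_ns * 1e3)          # tau_e bounded by tau_R
  ts_max <- min(5, tau_r_ns)
  switch(as.character(model),
    "1" = list(lower = 0, upper = 1, grid = as.matrix(s2g)),
    "2" = list(lower = c(0, 0), upper = c(1, te_max),
               grid = as.matrix(expand.grid(s2g, teg))),
    "3" = list(lower = c(0, 0), upper = c(1, 30),
               grid = as.matrix(expand.grid(s2g, rxg))),
    "4" = list(lower = c(0, 0, 0), upper = c(1, te_max, 30),
               grid = as.matrix(expand.grid(s2g, teg, rxg))),
    "5" = list(lower = c(0, 0, 0.05), upper = c(1, 1, ts_max),
               grid = as.matrix(expand.grid(seq(0.5, 1, by = 0.1), s2g,
                                            c(0.2, 0.5, 1, 2)))))
}

# Multistart bounded least squares for one model on one residue.
# pobs: prepared observables from .prep_obs().
#' @keywords internal
.fit_one_model <- function(model, pobs, pre, tau_r_ns, n_starts = 3L) {
  sp <- .model_search_space(model, tau_r_ns)
  fn <- function(th) .residue_chi2(model, th, pobs, pre)
  gv <- apply(sp$grid, 1L, fn)
  starts <- sp$grid[order(gv)[seq_len(min(n_starts, nrow(sp$grid)))], ,
                    drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(starts[i, ], sp$lower), sp$upper)
    o <- if (length(th0) == 1L) {
      op <- stats::optimize(fn, lower = sp$lower, upper = sp$upper)
      list(par = op$minimum, value = op$objective)
    } else {
      stats::optim(th0, fn, method = "L-BFGS-B",
                   lower = sp$lower, upper = sp$upper,
                   control = list(maxit = 200))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(model = model, theta = best$par, chi2 = best$value,
       npar = .model_npar[[as.character(model)]])
}

# F-test p-value between nested fits (f1 simpler than f2).
#' @keywords internal
.ftest_p <- function(f1, f2, n_obs) {
  df2 <- n_obs - f2$npar
  dp <- f2$npar - f1$npar
  if (df2 < 1L || dp < 1L) return(NA_real_)
  if (f2$chi2 <= 0) return(0)
  f <- ((f1$chi2 - f2$chi2) / dp) / (f2$chi2 / df2)
  if (!is.finite(f) || f < 0) return(1)
  stats::pf(f, dp, df2, lower.tail = FALSE)
}

#' @keywords internal
.gof_p <- function(fit, n_obs) {
  df <- n_obs - fit$npar
  if (df < 1L) return(NA_real_)
  stats::pchisq(fit$chi2, df, lower.tail = FALSE)
}

# Stepwise Mandel-style selection: accept model 1 on goodness of fit alone;
# otherwise require a significant F improvement plus adequate fit for 2/3,
# then 4, then 5; fall back to the best adequately fitting model; flag the
# residue when nothing fits.
#' @keywords internal
.select_model <- function(fits, n_obs, alpha_gof, alpha_f) {
  get <- function(m) fits[[as.character(m)]]
  ok_gof <- function(f) {
    p <- .gof_p(f, n_obs)
    !is.na(p) && p > alpha_gof
  }
  if (!is.null(get(1)) && ok_gof(get(1))) return(list(model = 1L, status = "ok"))
  cand23 <- Filter(function(m) {
    f <- get(m)
    !is.null(f) && !is.null(get(1)) &&
      isTRUE(.ftest_p(get(1), f, n_obs) < alpha_f) && ok_gof(f)
  }, c(2L, 3L))
  if (length(cand23) > 0) {
    chis <- vapply(cand23, function(m) get(m)$chi2, 1.0)
    return(list(model = cand23[which.min(chis)], status = "ok"))
  }
  base23 <- Filter(function(m) !is.null(get(m)), c(2L, 3L))
  if (!is.null(get(4)) && length(base23) > 0) {
    chis <- vapply(base23, function(m) get(m)$chi2, 1.0)
    ref <- get(base23[which.min(chis)])
    if (isTRUE(.ftest_p(ref, get(4), n_obs) < alpha_f) && ok_gof(get(4)))
      return(list(model = 4L, status = "ok"))
  }
  if (!is.null(get(5)) && ok_gof(get(5)))
    return(list(model = 5L, status = "ok"))
  # fallback: best adequately fitting model by AIC, else unsatisfactory
  ok <- Filter(function(m) ok_gof(get(m)), as.integer(names(fits)))
  if (length(ok) > 0) {
    aic <- vapply(ok, function(m) get(m)$chi2 + 2 * get(m)$npar, 1.0)
    return(list(model = ok[which.min(aic)], status = "ok"))
  }
  aic <- vapply(as.integer(names(fits)),
                function(m) get(m)$chi2 + 2 * get(m)$npar, 1.0)
  list(model = as.integer(names(fits))[which.min(aic)], status = "no_model")
}

#' @keywords internal
.aic_select <- function(fits, n_obs) {
  ms <- as.integer(names(fits))
  aic <- vapply(ms, function(m) fits[[as.character(m)]]$chi2 +
                  2 * fits[[as.character(m)]]$npar, 1.0)
  list(model = ms[which.min(aic)], status = "ok")
}

# theta vector -> result row fields for the output table.
#' @keywords internal
.theta_fields <- function(model, theta, rex_ref_mhz) {
  out <- list(s2 = NA_real_, tau_e_ps = NA_real_, rex = NA_real_,
              s2f = NA_real_, s2s = NA_real_, tau_s_ns = NA_real_)
  if (model %in% 1:4) out$s2 <- theta[1]
  if (model %in% c(2, 4)) out$tau_e_ps <- theta[2]
  if (model == 3) out$rex <- theta[2]
  if (model == 4) out$rex <- theta[3]
  if (model == 5) {
    out$s2f <- theta[1]; out$s2s <- theta[2]; out$tau_s_ns <- theta[3]
    out$s2 <- theta[1] * theta[2]
  }
  out
}

#' Fit model-free parameters residue by residue
#'
#' For every residue with sufficient data, fits the nested model-free
#' models in the order 1, 2, 3, 4, 5 (each by deterministic coarse-grid
#' multistart bounded least squares against all available observables at
#' all fields) and selects one model.  The default protocol is a stepwise
#' Mandel-style chi-square goodness-of-fit / F-test scheme with
#' significance levels `alpha_gof` (default 0.10) and `alpha_f` (default
#' 0.20); `protocol = "aic"` selects by minimum AIC instead.  Exchange
#' contributions are parameterized at `rex_ref_mhz` and scaled to each
#' measurement field by the field-squared rule.
#'
#' Residues flagged `proline`, `overlapped` or `missing` are excluded;
#' residues with fewer observables than the smallest model's parameters
#' plus one are skipped with a warning; residues for which no model
#' achieves an adequate fit are flagged `"no_model"` (their best-AIC
#' parameters are still reported).  Parameter uncertainties come from
#' Monte-Carlo resampling: `mc_reps` synthetic observable sets are drawn
#' from Gaussians centered on the fitted values with the experimental
#' sigmas and refit with the selected model.
#'
#' @param dataset A [relaxation_dataset()].
#' @param tensor A [diffusion_tensor()], typically from [fit_diffusion()].
#' @param constants A [nuclear_constants()] object.
#' @param models Integer subset of 1:5 to consider.
#' @param protocol `"ftest"` (stepwise, default) or `"aic"`.
#' @param alpha_gof,alpha_f Significance levels of the goodness-of-fit and
#'   F tests.
#' @param mc_reps Monte-Carlo draws for uncertainties (0 disables).
#' @param seed Integer seed for the Monte-Carlo resampling.
#' @param rex_ref_mhz Reference field (MHz) at which fitted `rex` values
#'   are reported.
#' @param nh_orientations Optional matrix of NH unit vectors (rows named by
#'   residue id), required for an axially symmetric tensor.
#' @return Object of classes `mf_fit` and `data.frame`: one row per
#'   residue with the selected model, parameters, Monte-Carlo
#'   uncertainties, `chi2`, `df`, `gof_p`, `n_obs` and `status`; the
#'   tensor, constants and call settings are attached as attributes.
#' @export
fit_residue_models <- function(dataset, tensor,
                               constants = nuclear_constants(),
                               models = 1:5,
                               protocol = c("ftest", "aic"),
                               alpha_gof = 0.10, alpha_f = 0.20,
                               mc_reps = 500L, seed = 1L,
                               rex_ref_mhz = 800,
                               nh_orientations = NULL) {
  stopifnot(inherits(dataset, "relaxation_dataset"),
            inherits(tensor, "diffusion_tensor"))
  protocol <- match.arg(protocol)
  if (tensor$kind == "axially_symmetric" && is.null(nh_orientations))
    stop("nh_orientations are required with an axially symmetric tensor")
  excl <- .excluded_residues(dataset)
  resids <- sort(unique(dataset$residue_id))
  temperature_k <- attr(dataset, "temperature_k")

  rows <- vector("list", length(resids))
  skipped <- integer(0)
  for (i in seq_along(resids)) {
    rid <- resids[i]
    rname <- dataset$residue_name[match(rid, dataset$residue_id)]
    row <- data.frame(residue_id = rid, residue_name = rname, model = NA_integer_,
                      s2 = NA_real_, s2_err = NA_real_,
                      tau_e_ps = NA_real_, tau_e_err = NA_real_,
                      rex = NA_real_, rex_err = NA_real_,
                      rex_field_mhz = rex_ref_mhz,
                      s2f = NA_real_, s2f_err = NA_real_,
                      s2s = NA_real_, s2s_err = NA_real_,
                      tau_s_ns = NA_real_, tau_s_err = NA_real_,
                      chi2 = NA_real_, df = NA_integer_, gof_p = NA_real_,
                      n_obs = 0L, status = "excluded_flag",
                      stringsAsFactors = FALSE)
    if (rid %in% excl) { rows[[i]] <- row; next }
    obs <- .residue_observables(dataset, rid)
    n_obs <- if (is.null(obs)) 0L else nrow(obs)
    row$n_obs <- n_obs
    if (n_obs < 2L) {
      row$status <- "skipped_insufficient"
      skipped <- c(skipped, rid)
      rows[[i]] <- row
      next
    }
    nh <- if (!is.null(nh_orientations)) {
      v <- nh_orientations[as.character(rid), ]
      if (any(!is.finite(v))) { row$status <- "skipped_insufficient"
        skipped <- c(skipped, rid); rows[[i]] <- row; next }
      v
    } else NULL
    pre <- .fit_precompute(unique(obs$field_mhz), tensor, constants, nh,
                           temperature_k, rex_ref_mhz)
    pobs <- .prep_obs(obs, pre)
    feasible <- models[.model_npar[as.character(models)] < n_obs]
    if (length(feasible) == 0L) {
      row$status <- "skipped_insufficient"
      skipped <- c(skipped, rid)
      rows[[i]] <- row
      next
    }
    fits <- lapply(feasible, .fit_one_model, pobs = pobs, pre = pre,
                   tau_r_ns = tensor$tau_r_ns)
    names(fits) <- as.character(feasible)
    sel <- if (protocol == "ftest") {
      .select_model(fits, n_obs, alpha_gof, alpha_f)
    } else .aic_select(fits, n_obs)
    chosen <- fits[[as.character(sel$model)]]
    tf <- .theta_fields(sel$model, chosen$theta, rex_ref_mhz)
    row$model <- sel$model
    row[names(tf)] <- tf
    row$chi2 <- chosen$chi2
    row$df <- n_obs - chosen$npar
    row$gof_p <- .gof_p(chosen, n_obs)
    row$status <- sel$status
    rows[[i]] <- list(row = row, pobs = pobs, pre = pre, fit = chosen)
  }
  if (length(skipped) > 0)
    warning("residues skipped (too few observables): ",
            paste(skipped, collapse = ", "))

  # Monte-Carlo uncertainties for successfully fitted residues
  out <- lapply(rows, function(x) if (is.data.frame(x)) x else x$row)
  if (mc_reps > 0L) {
    .with_seed(seed, {
      for (i in seq_along(rows)) {
        x <- rows[[i]]
        if (is.data.frame(x)) next
        # map per-theta sd onto the named error columns
        sds <- .mc_errors(x$fit, x$pobs, x$pre, tensor$tau_r_ns, mc_reps)
        m <- x$fit$model
        if (m %in% 1:4) out[[i]]$s2_err <- sds[1]
        if (m %in% c(2, 4)) out[[i]]$tau_e_err <- sds[2]
        if (m == 3) out[[i]]$rex_err <- sds[2]
        if (m == 4) out[[i]]$rex_err <- sds[3]
        if (m == 5) {
          out[[i]]$s2f_err <- sds[1]; out[[i]]$s2s_err <- sds[2]
          out[[i]]$tau_s_err <- sds[3]
          out[[i]]$s2_err <- stats::sd(attr(sds, "s2_draws"))
        }
      }
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, tensor = tensor, constants = constants,
            protocol = protocol, alpha_gof = alpha_gof, alpha_f = alpha_f,
            mc_reps = mc_reps, seed = seed,
            class = c("mf_fit", "data.frame"))
}

# Monte-Carlo resampling around the fitted predictions.
#' @keywords internal
.mc_errors <- function(fit, pobs, pre, tau_r_ns, reps) {
  mo <- .theta_to_motion(fit$model, fit$theta)
  pred <- lapply(pobs, function(po) {
    if (length(po$types) == 0L) return(numeric(0))
    tr <- .fast_triple(mo$s2, mo$amp, mo$tau_int_s, mo$rex, po$fp,
                       pre$tensor_terms, pre$gamma_ratio)
    unname(tr[po$types])
  })
  sp <- .model_search_space(fit$model, tau_r_ns)
  th0 <- pmin(pmax(fit$theta, sp$lower), sp$upper)
  draws <- matrix(NA_real_, reps, fit$npar)
  for (r in seq_len(reps)) {
    ob <- pobs
    for (k in seq_along(ob))
      ob[[k]]$values <- stats::rnorm(length(pred[[k]]), pred[[k]],
                                     ob[[k]]$sigmas)
    fn <- function(th) .residue_chi2(fit$model, th, ob, pre)
    o <- if (fit$npar == 1L) {
      op <- stats::optimize(fn, lower = sp$lower, upper = sp$upper)
      list(par = op$minimum)
    } else {
      stats::optim(th0, fn, method = "L-BFGS-B", lower = sp$lower,
                   upper = sp$upper, control = list(maxit = 100))
    }
    draws[r, ] <- o$par
  }
  sds <- apply(draws, 2L, stats::sd)
  if (fit$model == 5L) attr(sds, "s2_draws") <- draws[, 1] * draws[, 2]
  sds
}

#' @export
print.mf_fit <- function(x, ...) {
  ok <- sum(x$status == "ok")
  cat(sprintf("Model-free fit: %d residues (%d ok, %d flagged), tau_R = %.2f ns (%s)\n",
              nrow(x), ok, nrow(x) - ok,
              attr(x, "tensor")$tau_r_ns, attr(x, "tensor")$kind))
  cat("  models: ",
      paste(sprintf("#%s x%d", names(table(x$model)), table(x$model)),
            collapse = ", "), "\n")
  NextMethod()
}

# Evaluate code with a temporary RNG state; restores the caller's state.
#' @keywords internal
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
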