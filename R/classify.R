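# Threshold classification of per-residue motions and Cys-anchored
# region aggregation.

#' Exchange-contribution threshold at a given field
#'
#' The field-dependent threshold above which an exchange contribution to
#' R2 marks a us-ms motion site: anchored at 3.0 s^-1 at 800 MHz and
#' scaled with the square of the field, giving 2.3 s^-1 at 700 MHz and
#' 1.7 s^-1 at 600 MHz as conventionally reported (one decimal).  The
#' exact value is returned; the rounded reporting value is attached as
#' attribute `reported`.
#'
#' @param field_mhz 1H frequency in MHz.
#' @param anchor Threshold (s^-1) at `anchor_mhz`.
#' @param anchor_mhz Anchor field in MHz.
#' @return Exact threshold in s^-1 with attribute `reported`.
#' @examples
#' rex_threshold(600)  # 1.6875, reported 1.7
#' @export
rex_threshold <- function(field_mhz, anchor = 3.0, anchor_mhz = 800) {
  if (any(!is.finite(field_mhz)) || any(field_mhz <= 0))
    stop("field_mhz must be positive")
  exact <- rex_at_field(anchor, anchor_mhz, field_mhz)
  structure(exact, reported = round(exact, 1))
}

.dynamics_labels <- c("fast_ps_ns", "us_ms_exchange", "ms_s_two_conformers",
                      "broadened", "no_data", "ordered")

#' Classify the motional regime of one residue
#'
#' Applies the threshold rules used for the per-residue dynamics maps:
#'
#' * `fast_ps_ns`: high-amplitude ps-ns motion, S2 < `s2_threshold`
#'   (default 0.8).  For model 5 the rule is "any of S2f, S2s or their
#'   product < 0.8", reflecting the caveat that extended-model order
#'   parameters are not directly comparable with models 1-4.
#' * `us_ms_exchange`: fitted exchange contribution, scaled to
#'   `classify_at_mhz` (default 800), above [rex_threshold()] at that
#'   field.
#' * `ms_s_two_conformers`: doubled resonances (`doubled` flag) - slow
#'   ms-s exchange between conformers.
#' * `broadened`: significant amide signal broadening (`broadened` flag).
#' * `no_data`: proline, overlapped or missing (mutually exclusive with
#'   all other labels).
#' * `ordered`: none of the above.
#'
#' @param params A [model_free_params()] or `NULL` when no fit exists.
#' @param flags Character vector (or comma-joined string) of record flags.
#' @param classify_at_mhz Field (MHz) at which the exchange rule is
#'   evaluated; exchange contributions are rescaled to it explicitly.
#' @param s2_threshold Order-parameter threshold.
#' @return Character vector of labels (subset of `fast_ps_ns`,
#'   `us_ms_exchange`, `ms_s_two_conformers`, `broadened`, `no_data`,
#'   `ordered`).
#' @examples
#' classify_residue(model_free_params(3, s2 = 0.9, rex = 4), character())
#' @export
classify_residue <- function(params = NULL, flags = character(),
                             classify_at_mhz = 800, s2_threshold = 0.8) {
  flags <- unlist(strsplit(paste(flags, collapse = ","), ",\\s*"))
  flags <- flags[flags != ""]
  if (any(flags %in% c("proline", "overlapped", "missing")))
    return("no_data")
  labels <- character(0)
  if (!is.null(params)) {
    stopifnot(inherits(params, "model_free_params"))
    fast <- if (params$model_id == 5L) {
      params$s2f < s2_threshold || params$s2s < s2_threshold ||
        params$s2 < s2_threshold
    } else params$s2 < s2_threshold
    if (fast) labels <- c(labels, "fast_ps_ns")
    if (!is.null(params$rex)) {
      rex_here <- rex_at_field(params$rex, params$rex_field_mhz,
                               classify_at_mhz)
      if (rex_here > as.numeric(rex_threshold(classify_at_mhz)))
        labels <- c(labels, "us_ms_exchange")
    }
  }
  if ("doubled" %in% flags) labels <- c(labels, "ms_s_two_conformers")
  if ("broadened" %in% flags) labels <- c(labels, "broadened")
  if (length(labels) == 0L) labels <- "ordered"
  labels
}

#' Classify every fitted residue of a model-free fit
#'
#' Convenience wrapper applying [classify_residue()] across an [mf_fit]
#' table, joining in the dataset flags.  Returns one row per residue with
#' comma-joined labels, S2 and the exchange contribution rescaled to the
#' classification field.
#'
#' @param fit An `mf_fit` from [fit_residue_models()].
#' @param dataset The [relaxation_dataset()] the fit came from (for
#'   flags); optional.
#' @inheritParams classify_residue
#' @return Data frame `residue_id`, `labels`, `s2`, `rex_at_classify`,
#'   `model`, `status`.
#' @export
classify_dynamics <- function(fit, dataset = NULL, classify_at_mhz = 800,
                              s2_threshold = 0.8) {
  stopifnot(inherits(fit, "mf_fit"))
  rows <- lapply(seq_len(nrow(fit)), function(i) {
    r <- fit[i, ]
    flags <- character(0)
    if (!is.null(dataset)) {
      fl <- dataset$flags[dataset$residue_id == r$residue_id]
      flags <- unique(unlist(strsplit(fl[fl != "" & !is.na(fl)], ",\\s*")))
    }
    params <- NULL
    if (!is.na(r$model) && r$status %in% c("ok", "no_model")) {
      params <- switch(as.character(r$model),
        "1" = model_free_params(1, s2 = r$s2),
        "2" = model_free_params(2, s2 = r$s2, tau_e_ps = r$tau_e_ps),
        "3" = model_free_params(3, s2 = r$s2, rex = r$rex,
                                rex_field_mhz = r$rex_field_mhz),
        "4" = model_free_params(4, s2 = r$s2, tau_e_ps = r$tau_e_ps,
                                rex = r$rex, rex_field_mhz = r$rex_field_mhz),
        "5" = model_free_params(5, s2f = r$s2f, s2s = r$s2s,
                                tau_s_ns = r$tau_s_ns))
    }
    if (r$status %in% c("excluded_flag", "skipped_insufficient") &&
        length(flags) == 0)
      flags <- "missing"
    labels <- classify_residue(params, flags, classify_at_mhz, s2_threshold)
    rex_cl <- if (!is.null(params) && !is.null(params$rex))
      rex_at_field(params$rex, params$rex_field_mhz, classify_at_mhz)
    else NA_real_
    data.frame(residue_id = r$residue_id,
               labels = paste(labels, collapse = ","),
               s2 = if (is.null(params)) NA_real_ else params$s2,
               rex_at_classify = rex_cl,
               model = r$model, status = r$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "classify_at_mhz") <- classify_at_mhz
  attr(out, "s2_threshold") <- s2_threshold
  out
}

#' Elevated R1*R2 product indicator
#'
#' Advisory flag for latent us-ms exchange: residues whose R1*R2 product
#' at one field exceeds the 10%-trimmed mean plus one trimmed standard
#' deviation of the population.  The R1*R2 product cancels most of the
#' order-parameter dependence, so elevated values single out
#' exchange-broadened sites.  Not used in the headline classification.
#'
#' @param dataset A [relaxation_dataset()].
#' @param field_mhz Field to evaluate at (default: highest with both
#'   rates).
#' @param trim Trim fraction for the population statistics.
#' @param n_sd Number of trimmed SDs above the trimmed mean.
#' @return Data frame `residue_id`, `r1r2`, `elevated`.
#' @export
r1r2_indicator <- function(dataset, field_mhz = NULL, trim = 0.1, n_sd = 1) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  has_both <- !is.na(dataset$r1) & !is.na(dataset$r2)
  if (is.null(field_mhz)) {
    fields <- unique(dataset$field_mhz[has_both])
    if (length(fields) == 0L) stop("no field with both R1 and R2 present")
    field_mhz <- max(fields)
  }
  rec <- dataset[dataset$field_mhz == field_mhz & has_both, , drop = FALSE]
  prod <- rec$r1 * rec$r2
  out <- data.frame(residue_id = rec$residue_id, r1r2 = prod,
                    elevated = FALSE)
  if (nrow(rec) < 3L) {
    warning("too few residues for R1*R2 population statistics; no flags set")
    return(out)
  }
  thr <- mean(prod, trim = trim) + n_sd * .trimmed_sd(prod, trim)
  # strict comparison with an ulp-scale guard so a perfectly homogeneous
  # population never self-flags
  out$elevated <- prod > thr + 1e-9 * abs(thr)
  attr(out, "threshold") <- thr
  attr(out, "field_mhz") <- field_mhz
  out
}

#' Define Cys-anchored protein regions
#'
#' The region scheme used for aggregating order parameters and ensemble
#' RMSDs over the three-finger architecture: three loops ("fingers"), an
#' optional C-terminal tail, and the "head" - every remaining residue
#' except the first one (which carries no amide and is excluded).  Loop
#' boundaries are conventionally anchored on the invariant Cys positions
#' of the fold; since exact boundaries are protein-specific they are
#' supplied explicitly (or via [read_region_scheme()]) and every
#' aggregate echoes the scheme that produced it.
#'
#' @param loop_i,loop_ii,loop_iii Integer residue-id vectors.
#' @param c_tail Optional integer residue-id vector.
#' @param residue_ids All residue ids of the protein (defines the head).
#' @param exclude Residues excluded from every region (default: the first
#'   residue).
#' @return Object of class `region_scheme`: list with `regions` (named
#'   list of residue-id vectors incl. `head`) and `excluded`.
#' @examples
#' region_scheme(6:16, 26:45, 55:70, c_tail = 86:100, residue_ids = 1:100)
#' @export
region_scheme <- function(loop_i, loop_ii, loop_iii, c_tail = NULL,
                          residue_ids, exclude = min(residue_ids)) {
  regions <- list(loop_i = as.integer(loop_i), loop_ii = as.integer(loop_ii),
                  loop_iii = as.integer(loop_iii))
  if (!is.null(c_tail) && length(c_tail) > 0)
    regions$c_tail <- as.integer(c_tail)
  all_named <- unlist(regions)
  if (anyDuplicated(all_named))
    stop("regions overlap: ", paste(unique(all_named[duplicated(all_named)]),
                                    collapse = ", "))
  outside <- setdiff(all_named, residue_ids)
  if (length(outside) > 0)
    stop("region residues outside the sequence: ",
         paste(outside, collapse = ", "))
  head <- setdiff(residue_ids, c(all_named, exclude))
  regions$head <- as.integer(sort(head))
  structure(list(regions = regions, excluded = as.integer(exclude),
                 residue_ids = as.integer(sort(residue_ids))),
            class = "region_scheme")
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("Region scheme:\n")
  for (rg in names(x$regions)) {
    r <- x$regions[[rg]]
    cat(sprintf("  %-8s %d residues (%s)\n", rg, length(r),
                paste(range(r), collapse = "-")))
  }
  cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Region-wise mean of a per-residue quantity
#'
#' Arithmetic mean over the residues of each region that carry data,
#' reporting both the number available and the region size (the two
#' numbers annotated on region bar plots).  A region with no data yields
#' `NA` with a warning rather than an error, mirroring how a loop without
#' experimental coverage is reported with a caveat rather than dropped.
#'
#' @param values Named numeric vector (names = residue ids) or a data
#'   frame with `residue_id` and a value column.
#' @param scheme A [region_scheme()].
#' @param value_col Column to aggregate when `values` is a data frame.
#' @return Data frame `region`, `mean`, `n_available`, `n_total`.
#' @export
region_mean <- function(values, scheme, value_col = "s2") {
  stopifnot(inherits(scheme, "region_scheme"))
  if (is.data.frame(values)) {
    v <- values[[value_col]]
    names(v) <- values$residue_id
    values <- v
  }
  if (is.null(names(values)))
    stop("values must be named by residue id")
  ids <- as.integer(names(values))
  out <- lapply(names(scheme$regions), function(rg) {
    rr <- scheme$regions[[rg]]
    have <- ids %in% rr & !is.na(values)
    m <- if (any(have)) mean(values[have]) else NA_real_
    if (!any(have))
      warning(sprintf("region %s has no data; mean is NA", rg))
    data.frame(region = rg, mean = m, n_available = sum(have),
               n_total = length(rr), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
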