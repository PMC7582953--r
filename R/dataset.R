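# The relaxation dataset container: per-residue, per-field R1/R2/NOE
# records with uncertainties and annotations.

.known_flags <- c("broadened", "doubled", "overlapped", "proline", "missing")

#' Build a relaxation dataset
#'
#' A relaxation dataset is a validated data frame of per-residue,
#' per-field records with columns `residue_id`, `residue_name`,
#' `field_mhz`, `r1`, `r1_err`, `r2`, `r2_err`, `noe`, `noe_err` and
#' `flags` (comma-separated annotations from `broadened`, `doubled`,
#' `overlapped`, `proline`, `missing`), plus `protein` and `temperature_k`
#' attributes.  Missing observables are `NA` with `NA` uncertainty;
#' present observables must carry a positive uncertainty.  Author residue
#' numbering is preserved (an N-terminal expression Met numbered 0 is
#' allowed); at most one record per (residue, field) is permitted.
#'
#' @param records Data frame with the columns above (`residue_name` and
#'   `flags` optional).
#' @param protein Protein name.
#' @param temperature_k Sample temperature (K), shared by all records.
#' @return Object of classes `relaxation_dataset` and `data.frame`.
#' @export
relaxation_dataset <- function(records, protein = "unknown",
                               temperature_k = 310.15) {
  stopifnot(is.data.frame(records))
  req <- c("residue_id", "field_mhz", "r1", "r1_err", "r2", "r2_err",
           "noe", "noe_err")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"residue_name" %in% names(records))
    records$residue_name <- rep(NA_character_, nrow(records))
  if (!"flags" %in% names(records))
    records$flags <- rep("", nrow(records))
  records$flags[is.na(records$flags)] <- ""
  records$residue_id <- as.integer(records$residue_id)
  if (nrow(records) > 0) {
    if (any(!is.finite(records$field_mhz)) || any(records$field_mhz <= 0))
      stop("field_mhz must be positive")
    key <- paste(records$residue_id, records$field_mhz)
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop(sprintf("duplicate record for residue %d at %g MHz (row %d)",
                   records$residue_id[d], records$field_mhz[d], d))
    }
    for (v in c("r1", "r2", "noe")) {
      err <- records[[paste0(v, "_err")]]
      bad <- !is.na(records[[v]]) & (is.na(err) | err <= 0)
      if (any(bad))
        stop(sprintf("%s present without positive %s_err at rows: %s",
                     v, v, paste(which(bad), collapse = ", ")))
    }
    bad_flags <- setdiff(unlist(strsplit(records$flags[records$flags != ""],
                                         ",\\s*")), .known_flags)
    if (length(bad_flags) > 0)
      stop("unknown flags: ", paste(unique(bad_flags), collapse = ", "))
  }
  records <- records[, c("residue_id", "residue_name", "field_mhz",
                         "r1", "r1_err", "r2", "r2_err", "noe", "noe_err",
                         "flags")]
  records <- records[order(records$residue_id, records$field_mhz), ]
  rownames(records) <- NULL
  structure(records, protein = protein, temperature_k = temperature_k,
            class = c("relaxation_dataset", "data.frame"))
}

#' @export
print.relaxation_dataset <- function(x, ...) {
  cat(sprintf("Relaxation dataset: %s, T = %.2f K\n",
              attr(x, "protein"), attr(x, "temperature_k")))
  cat(sprintf("  %d records, %d residues, fields: %s MHz\n",
              nrow(x), length(unique(x$residue_id)),
              paste(sort(unique(x$field_mhz)), collapse = ", ")))
  NextMethod()
}

# TRUE for records whose flags contain any of `which`.
#' @keywords internal
.has_flag <- function(flags, which) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ",\\s*"),
         function(f) any(f %in% which), logical(1))
}

# Residues excluded from per-residue fitting: proline, overlapped, missing.
#' @keywords internal
.excluded_residues <- function(dataset,
                               flags = c("proline", "overlapped", "missing")) {
  unique(dataset$residue_id[.has_flag(dataset$flags, flags)])
}

# Per-residue observable table used by the fitting routines: one row per
# observable with field, type (r1/r2/noe), value, sigma.
#' @keywords internal
.residue_observables <- function(dataset, residue_id) {
  rec <- dataset[dataset$residue_id == residue_id, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(rec))) {
    for (v in c("r1", "r2", "noe")) {
      val <- rec[[v]][i]
      if (!is.na(val)) {
        out <- rbind(out, data.frame(field_mhz = rec$field_mhz[i], type = v,
                                     value = val,
                                     sigma = rec[[paste0(v, "_err")]][i]))
      }
    }
  }
  out
}
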