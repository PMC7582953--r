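# Readers and writers: relaxation TSV, fit-result TSV, region-scheme
# config, FASTA, multi-model PDB, and a minimal NMR-STAR relaxation
# reader for deposited (BMRB) validation data.
#
# Canonical tabular dialect: UTF-8 tab-separated values with a header row
# and '#' comment lines.

#' Read a relaxation dataset from TSV
#'
#' Expects tab-separated columns `residue_id`, `residue_name`,
#' `field_mhz`, `r1`, `r1_err`, `r2`, `r2_err`, `noe`, `noe_err`,
#' `flags` (empty string for none); `#` lines are comments; empty cells
#' are missing values.  All validation of [relaxation_dataset()] applies;
#' malformed records are rejected with the offending row named, never
#' silently coerced.
#'
#' @param path File path.
#' @param protein,temperature_k Dataset attributes (may also be given as
#'   `# protein:` / `# temperature_k:` comment headers in the file).
#' @return A [relaxation_dataset()].
#' @export
read_relaxation_tsv <- function(path, protein = NULL, temperature_k = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- .read_comment_headers(path)
  if (is.null(protein)) protein <- hdr[["protein"]] %||% "unknown"
  if (is.null(temperature_k))
    temperature_k <- as.numeric(hdr[["temperature_k"]] %||% "310.15")
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("residue_id", "field_mhz", "r1", "r1_err", "r2", "r2_err",
           "noe", "noe_err")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  for (col in req) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & v != "" & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad) > 0)
        stop(sprintf("%s: non-numeric %s at data row(s): %s", path, col,
                     paste(bad, collapse = ", ")))
      df[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  relaxation_dataset(df, protein = protein, temperature_k = temperature_k)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# "# key: value" comment headers at the top of a TSV file.
#' @keywords internal
.read_comment_headers <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_]+):\\s*(.+)$", l))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write a relaxation dataset to TSV
#'
#' Inverse of [read_relaxation_tsv()]; the protein name and temperature
#' are stored as `# key: value` comment headers so the round trip is
#' lossless.
#'
#' @param dataset A [relaxation_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relaxation_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# protein: %s", attr(dataset, "protein")),
               sprintf("# temperature_k: %.6g", attr(dataset, "temperature_k"))),
             con)
  utils::write.table(as.data.frame(dataset), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a model-free fit result to TSV
#'
#' One row per residue: selected model, parameters with uncertainties,
#' chi-square and status; fit settings (tensor, constants, protocol,
#' seed) are embedded as comment headers for provenance.
#'
#' @param fit An `mf_fit` from [fit_residue_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "mf_fit"))
  tensor <- attr(fit, "tensor")
  constants <- attr(fit, "constants")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tensor: %s tau_r_ns=%.6g anisotropy=%.6g", tensor$kind,
            tensor$tau_r_ns, tensor$anisotropy),
    sprintf("# constants: r_nh_angstrom=%.6g csa_ppm=%.6g",
            constants$r_nh_angstrom, constants$csa_ppm),
    sprintf("# protocol: %s alpha_gof=%.3g alpha_f=%.3g mc_reps=%d seed=%d",
            attr(fit, "protocol"), attr(fit, "alpha_gof"),
            attr(fit, "alpha_f"), attr(fit, "mc_reps"), attr(fit, "seed"))),
    con)
  utils::write.table(as.data.frame(fit), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a region scheme from a YAML config
#'
#' Config keys: `loop_i`, `loop_ii`, `loop_iii`, optional `c_tail`, each
#' either an explicit integer vector or a `[first, last]` range given as
#' `first-last` string; plus `residues` (total range) and optional
#' `exclude`.
#'
#' @param path YAML file path.
#' @return A [region_scheme()].
#' @export
read_region_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  parse_range <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L && grepl("-", x)) {
      b <- as.integer(strsplit(x, "-")[[1]])
      return(seq(b[1], b[2]))
    }
    as.integer(unlist(x))
  }
  need <- c("loop_i", "loop_ii", "loop_iii", "residues")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop(path, ": missing region keys: ", paste(miss, collapse = ", "))
  resid <- parse_range(cfg$residues)
  region_scheme(parse_range(cfg$loop_i), parse_range(cfg$loop_ii),
                parse_range(cfg$loop_iii),
                c_tail = parse_range(cfg$c_tail),
                residue_ids = resid,
                exclude = parse_range(cfg$exclude) %||% min(resid))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of one-letter sequences.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], ""))
  names(out) <- names(seqs)
  out
}

#' Read a multi-model PDB file as a structure ensemble
#'
#' Splits MODEL/ENDMDL records, preserves author residue numbering
#' (Met0 = 0 accepted), keeps the first chain unless told otherwise,
#' ignores altlocs beyond the first and drops hydrogens unless
#' `keep_hydrogens`.  Models must agree in atom composition.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default: first chain present.
#' @param keep_hydrogens Keep hydrogen atoms (needed for NH vectors from
#'   explicit amide protons).
#' @return A [structure_ensemble()].
#' @export
read_pdb_ensemble <- function(path, chain = NULL, keep_hydrogens = TRUE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!keep_hydrogens) keep <- keep & !grepl("^H", trimws(at$elety))
  if (is.null(chain)) chain <- at$chain[keep][1]
  keep <- keep & (at$chain == chain | is.na(at$chain))
  at <- at[keep, , drop = FALSE]
  # collapse altlocs: keep the first occurrence of each (residue, atom)
  key <- paste(at$resno, at$elety)
  first <- !duplicated(key)
  at <- at[first, , drop = FALSE]
  idx <- which(keep)[first]
  nm <- dim(pdb$xyz)[1]
  coords <- array(NA_real_, dim = c(nrow(at), 3L, nm))
  for (m in seq_len(nm))
    coords[, , m] <- matrix(pdb$xyz[m, .atom2xyz(idx)], ncol = 3L,
                            byrow = TRUE)
  atoms <- data.frame(atom_name = trimws(at$elety),
                      residue_id = as.integer(at$resno),
                      residue_name = at$resid, chain = chain,
                      stringsAsFactors = FALSE)
  structure_ensemble(atoms, coords)
}

#' @keywords internal
.atom2xyz <- function(i) as.vector(t(cbind(3 * i - 2, 3 * i - 1, 3 * i)))

#' Write a structure ensemble as a multi-model PDB file
#'
#' Emits standard fixed-width ATOM records wrapped in MODEL/ENDMDL pairs,
#' preserving author residue numbering.  Coordinates are written at PDB
#' precision (0.001 Angstrom).
#'
#' @param ensemble A [structure_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  serial <- seq_len(nrow(at))
  elem <- substr(gsub("[0-9]", "", at$atom_name), 1, 1)
  for (m in seq_len(n_models(ensemble))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ensemble$coords[, , m]
    name4 <- ifelse(nchar(at$atom_name) < 4L,
                    sprintf(" %-3s", at$atom_name),
                    sprintf("%-4s", at$atom_name))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name4, at$residue_name, at$chain, at$residue_id,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read heteronuclear relaxation data from an NMR-STAR 3.1 file
#'
#' Minimal reader for the BMRB deposition format covering the
#' heteronuclear T1, T2 and NOE saveframe loops
#' (`_Heteronucl_T1_list` / `_T1`, `_Heteronucl_T2_list` / `_T2`,
#' `_Heteronucl_NOE_list` / `_Heteronucl_NOE`): extracts the residue
#' index, value and error columns and the spectrometer 1H frequency tag
#' of each saveframe, and maps them onto a [relaxation_dataset()].
#' Deposited T1/T2 values are read as rates (s^-1) when
#' `values_are_rates` (the convention of the relaxation depositions this
#' package targets) and inverted otherwise.  Unparseable loops are
#' rejected with an error naming the saveframe.
#'
#' @param path NMR-STAR 3.1 file path.
#' @param protein,temperature_k Dataset attributes.
#' @param values_are_rates Deposited T1/T2 columns hold R1/R2 rates
#'   rather than time constants.
#' @return A [relaxation_dataset()].
#' @export
read_nmrstar_relaxation <- function(path, protein = "bmrb",
                                    temperature_k = 310.15,
                                    values_are_rates = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- .split_saveframes(lines)
  rec <- list()
  for (fr in frames) {
    kind <- if (any(grepl("_Heteronucl_T1_list\\.", fr))) "r1"
    else if (any(grepl("_Heteronucl_T2_list\\.", fr))) "r2"
    else if (any(grepl("_Heteronucl_NOE_list\\.", fr))) "noe"
    else next
    freq <- .star_tag_value(fr, "Spectrometer_frequency_1H")
    if (is.na(freq))
      stop("saveframe without Spectrometer_frequency_1H tag (", kind, ")")
    prefix <- switch(kind, r1 = "_T1", r2 = "_T2", noe = "_Heteronucl_NOE")
    tab <- .star_loop_table(fr, prefix)
    if (is.null(tab))
      stop("unparseable ", kind, " loop in NMR-STAR file")
    idcol <- intersect(c("Comp_index_ID", "Seq_ID"), names(tab))[1]
    valcol <- intersect(c("Val", "Value", "T1_val", "T2_val"), names(tab))[1]
    errcol <- intersect(c("Val_err", "Value_err", "T1_val_err", "T2_val_err"),
                        names(tab))[1]
    if (is.na(idcol) || is.na(valcol))
      stop("missing residue-index or value column in ", kind, " loop")
    val <- as.numeric(tab[[valcol]])
    err <- if (!is.na(errcol)) as.numeric(tab[[errcol]]) else NA_real_
    if (kind %in% c("r1", "r2") && !values_are_rates) {
      err <- err / val^2    # sigma(1/T) = sigma(T)/T^2
      val <- 1 / val
    }
    name_col <- intersect(c("Comp_ID"), names(tab))[1]
    rec[[length(rec) + 1L]] <- data.frame(
      residue_id = as.integer(tab[[idcol]]),
      residue_name = if (!is.na(name_col)) tab[[name_col]] else NA_character_,
      field_mhz = as.numeric(freq), type = kind, value = val, err = err,
      stringsAsFactors = FALSE)
  }
  if (length(rec) == 0L)
    stop("no heteronuclear relaxation saveframes found in ", path)
  long <- do.call(rbind, rec)
  wide <- NULL
  for (key in unique(paste(long$residue_id, long$field_mhz))) {
    sub <- long[paste(long$residue_id, long$field_mhz) == key, ]
    row <- data.frame(residue_id = sub$residue_id[1],
                      residue_name = sub$residue_name[1],
                      field_mhz = sub$field_mhz[1],
                      r1 = NA_real_, r1_err = NA_real_,
                      r2 = NA_real_, r2_err = NA_real_,
                      noe = NA_real_, noe_err = NA_real_, flags = "",
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub))) {
      row[[sub$type[i]]] <- sub$value[i]
      row[[paste0(sub$type[i], "_err")]] <- sub$err[i]
    }
    wide <- rbind(wide, row)
  }
  relaxation_dataset(wide, protein = protein, temperature_k = temperature_k)
}

# Split NMR-STAR lines into saveframes (save_xxx ... save_).
#' @keywords internal
.split_saveframes <- function(lines) {
  starts <- grep("^\\s*save_\\S", lines)
  ends <- grep("^\\s*save_\\s*$", lines)
  frames <- list()
  for (s in starts) {
    e <- ends[ends > s][1]
    if (is.na(e)) e <- length(lines)
    frames[[length(frames) + 1L]] <- lines[s:e]
  }
  frames
}

# Value of a "_Something.Tag  value" free tag inside a saveframe.
#' @keywords internal
.star_tag_value <- function(fr, tag) {
  hit <- grep(paste0("\\.", tag, "\\b"), fr, value = TRUE)
  if (length(hit) == 0L) return(NA)
  parts <- strsplit(trimws(hit[1]), "\\s+")[[1]]
  if (length(parts) < 2L) return(NA)
  gsub("^['\"]|['\"]$", "", parts[2])
}

# Parse the loop whose column tags share `prefix` ("_T1", ...) into a
# data frame of character columns.
#' @keywords internal
.star_loop_table <- function(fr, prefix) {
  loops <- grep("^\\s*loop_\\s*$", fr)
  stops <- grep("^\\s*stop_\\s*$", fr)
  for (ls in loops) {
    le <- stops[stops > ls][1]
    if (is.na(le)) next
    body <- fr[(ls + 1):(le - 1)]
    tag_rows <- grep("^\\s*_", body)
    tags <- trimws(body[tag_rows])
    if (!any(startsWith(tags, paste0(prefix, ".")))) next
    cols <- sub("^_[^.]+\\.", "", tags)
    data_rows <- body[-tag_rows]
    data_rows <- data_rows[trimws(data_rows) != "" &
                             !startsWith(trimws(data_rows), "#")]
    if (length(data_rows) == 0L) return(NULL)
    mat <- lapply(data_rows, function(l) strsplit(trimws(l), "\\s+")[[1]])
    nc <- length(cols)
    if (any(vapply(mat, length, 1L) != nc)) return(NULL)
    df <- as.data.frame(do.call(rbind, mat), stringsAsFactors = FALSE)
    names(df) <- cols
    df[df == "." | df == "?"] <- NA
    return(df)
  }
  NULL
}
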