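# Multi-model NMR structure ensembles: container, superposition, disorder.

.backbone_atoms <- c("N", "CA", "C")

#' Build a structure ensemble
#'
#' Container for a multi-model (NMR-style) structure: an atom table shared
#' by all models plus a coordinate array.  Only the composition is
#' enforced; models must agree atom-for-atom in naming and numbering.
#' Author residue numbering is preserved (Met0 = residue 0 accepted).
#'
#' @param atoms Data frame with columns `atom_name`, `residue_id`,
#'   `residue_name` and optionally `chain`.
#' @param coords Numeric array `n_atoms x 3 x n_models` (Angstrom).
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            all(c("atom_name", "residue_id", "residue_name") %in% names(atoms)))
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  coords <- unclass(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_models array")
  if (dim(coords)[1] != nrow(atoms))
    stop("coords and atoms disagree on the number of atoms")
  if (any(!is.finite(coords))) stop("coords must be finite")
  atoms$residue_id <- as.integer(atoms$residue_id)
  structure(list(atoms = atoms, coords = coords),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d models, %d atoms, %d residues\n",
              n_models(x), nrow(x$atoms), length(unique(x$atoms$residue_id))))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble A `structure_ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(ensemble) dim(ensemble$coords)[3]

# Indices of backbone atoms (N, CA, C) restricted to a residue selection.
#' @keywords internal
.backbone_idx <- function(ensemble, residues = NULL) {
  idx <- which(ensemble$atoms$atom_name %in% .backbone_atoms)
  if (!is.null(residues))
    idx <- idx[ensemble$atoms$residue_id[idx] %in% residues]
  idx
}

#' Superpose a structure ensemble onto its iteratively refined mean
#'
#' Least-squares rigid-body superposition (Kabsch, proper rotations only)
#' of every model onto the mean structure, computed over the backbone
#' atoms (N, CA, C') of a residue selection - typically the stable,
#' well-ordered regions.  The mean is refined iteratively: superpose onto
#' the current mean, recompute the mean, repeat until the mean moves by
#' less than `tol` Angstrom or `max_iter` rounds are reached.
#'
#' @param ensemble A [structure_ensemble()].
#' @param selection Integer vector of residue ids used for the
#'   superposition (all residues by default).
#' @return The aligned ensemble, with the mean structure (matrix
#'   `n_atoms x 3`), the selection and the iteration count attached as
#'   attributes `mean_structure`, `selection`, `iterations`.
#' @export
superpose_ensemble <- function(ensemble, selection = NULL,
                               max_iter = 5L, tol = 1e-6) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (n_models(ensemble) < 2L) stop("at least 2 models are required")
  if (is.null(selection)) selection <- unique(ensemble$atoms$residue_id)
  if (length(selection) == 0L) stop("empty residue selection")
  sel_res <- selection[selection %in% ensemble$atoms$residue_id]
  if (length(sel_res) < length(selection))
    stop("selection residues absent from ensemble: ",
         paste(setdiff(selection, sel_res), collapse = ", "))
  idx <- .backbone_idx(ensemble, selection)
  got <- table(ensemble$atoms$residue_id[idx])
  short <- selection[!selection %in% names(got)[got == 3L]]
  if (length(short) > 0)
    stop("missing backbone atoms (N, CA, C) for residues: ",
         paste(short, collapse = ", "))

  nm <- n_models(ensemble)
  xyz <- t(apply(ensemble$coords, 3L, function(m) as.vector(t(m))))  # bio3d layout
  sel_xyz <- as.vector(t(cbind((idx - 1) * 3 + 1, (idx - 1) * 3 + 2,
                               (idx - 1) * 3 + 3)))
  mean_xyz <- colMeans(xyz)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    fitted <- bio3d::fit.xyz(fixed = mean_xyz, mobile = xyz,
                             fixed.inds = sel_xyz, mobile.inds = sel_xyz)
    new_mean <- colMeans(fitted)
    delta <- sqrt(max(rowSums(matrix(new_mean - mean_xyz, ncol = 3,
                                     byrow = TRUE)^2)))
    xyz <- fitted
    mean_xyz <- new_mean
    if (delta < tol) break
  }
  coords <- array(NA_real_, dim = dim(ensemble$coords))
  for (m in seq_len(nm))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  out <- structure_ensemble(ensemble$atoms, coords)
  attr(out, "mean_structure") <- matrix(mean_xyz, ncol = 3, byrow = TRUE)
  attr(out, "selection") <- selection
  attr(out, "iterations") <- iterations
  out
}

#' Per-residue displacement and region-wise RMSD of an aligned ensemble
#'
#' Computes, for an already superposed ensemble, the per-residue mean
#' backbone displacement (mean over models and backbone atoms of the
#' distance to the mean structure - the radius of a "sausage" rendering)
#' and the per-region backbone RMSD about the mean structure (root mean
#' square over models, atoms and residues of each region).  With
#' `all_pairs = TRUE` the region value is instead the all-pairs
#' inter-model RMSD, for cross-checking against tools that report it.
#'
#' @param ensemble A superposed [structure_ensemble()] (output of
#'   [superpose_ensemble()]).
#' @param scheme A [region_scheme()]; must use the ensemble numbering.
#' @param all_pairs Use all-pairs inter-model RMSD for regions.
#' @return Object of class `disorder_profile`: list with `per_residue`
#'   (data frame `residue_id`, `displacement`) and `per_region` (data
#'   frame `region`, `rmsd`, `n_residues`), tagged with the superposition
#'   selection used.
#' @export
disorder_profile <- function(ensemble, scheme, all_pairs = FALSE) {
  stopifnot(inherits(ensemble, "structure_ensemble"),
            inherits(scheme, "region_scheme"))
  mean_s <- attr(ensemble, "mean_structure")
  if (is.null(mean_s))
    stop("ensemble is not superposed; run superpose_ensemble() first")
  res_ids <- sort(unique(ensemble$atoms$residue_id))
  covered <- unlist(scheme$regions)
  missing <- setdiff(covered, res_ids)
  if (length(missing) > 0)
    stop("region scheme refers to residues absent from the ensemble: ",
         paste(missing, collapse = ", "))
  nm <- n_models(ensemble)

  disp <- vapply(res_ids, function(rid) {
    idx <- .backbone_idx(ensemble, rid)
    if (length(idx) == 0L) return(NA_real_)
    ref <- matrix(mean_s[idx, ], ncol = 3)
    d <- 0
    for (m in seq_len(nm)) {
      dd <- matrix(ensemble$coords[idx, , m], ncol = 3) - ref
      d <- d + mean(sqrt(rowSums(dd^2)))
    }
    d / nm
  }, 1.0)

  region_rmsd <- vapply(names(scheme$regions), function(rg) {
    idx <- .backbone_idx(ensemble, scheme$regions[[rg]])
    if (length(idx) == 0L) return(NA_real_)
    if (all_pairs) {
      tot <- 0; np <- 0
      for (a in seq_len(nm - 1)) for (b in (a + 1):nm) {
        dd <- matrix(ensemble$coords[idx, , a], ncol = 3) -
          matrix(ensemble$coords[idx, , b], ncol = 3)
        tot <- tot + mean(rowSums(dd^2))
        np <- np + 1
      }
      sqrt(tot / np)
    } else {
      ref <- matrix(mean_s[idx, ], ncol = 3)
      tot <- 0
      for (m in seq_len(nm)) {
        dd <- matrix(ensemble$coords[idx, , m], ncol = 3) - ref
        tot <- tot + mean(rowSums(dd^2))
      }
      sqrt(tot / nm)
    }
  }, 1.0)

  structure(list(
    per_residue = data.frame(residue_id = res_ids, displacement = disp),
    per_region = data.frame(region = names(scheme$regions),
                            rmsd = unname(region_rmsd),
                            n_residues = vapply(scheme$regions, length, 1L),
                            row.names = NULL),
    selection = attr(ensemble, "selection"),
    all_pairs = all_pairs),
    class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("Ensemble disorder profile",
      if (x$all_pairs) "(all-pairs RMSD)" else "(RMSD about the mean)", "\n")
  print(x$per_region, row.names = FALSE)
  invisible(x)
}

#' NH bond orientations from an ensemble model
#'
#' Unit vectors along the backbone amide N-H bonds of one ensemble model,
#' for use with axially symmetric diffusion tensors.  Uses the amide
#' hydrogen when present (atom `H` or `HN`); otherwise reconstructs the
#' N-H direction from heavy atoms as the external bisector of the
#' C'(i-1)-N-CA(i) angle.  The first residue (no preceding carbonyl) gets
#' `NA` unless its hydrogen is present.
#'
#' @param ensemble A [structure_ensemble()].
#' @param model Model index used for the coordinates.
#' @return Numeric matrix with one row per residue (rownames = residue
#'   ids) and columns x, y, z.
#' @export
nh_orientations <- function(ensemble, model = 1L) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atoms
  xyz <- ensemble$coords[, , model]
  res_ids <- sort(unique(at$residue_id))
  get <- function(rid, name) {
    i <- which(at$residue_id == rid & at$atom_name %in% name)
    if (length(i) == 0L) return(NULL)
    xyz[i[1], ]
  }
  out <- matrix(NA_real_, length(res_ids), 3,
                dimnames = list(res_ids, c("x", "y", "z")))
  for (k in seq_along(res_ids)) {
    rid <- res_ids[k]
    n <- get(rid, "N")
    if (is.null(n)) next
    h <- get(rid, c("H", "HN"))
    v <- if (!is.null(h)) {
      h - n
    } else {
      ca <- get(rid, "CA"); cp <- get(rid - 1L, "C")
      if (is.null(ca) || is.null(cp)) next
      u1 <- (n - ca) / sqrt(sum((n - ca)^2))
      u2 <- (n - cp) / sqrt(sum((n - cp)^2))
      u1 + u2
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) out[k, ] <- v / nv
  }
  out
}
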