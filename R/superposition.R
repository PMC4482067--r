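#' Root-mean-square deviation between two coordinate sets
#'
#' @param coords_a,coords_b N x 3 matrices of paired coordinates.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(coords_a, coords_b) {
  stopifnot(nrow(coords_a) == nrow(coords_b), nrow(coords_a) >= 1)
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Returns the proper rotation and translation minimizing the (optionally
#' weighted) sum of squared distances when mapping `coords_b` onto
#' `coords_a`.  The reflection branch of the SVD solution is corrected by
#' sign adjustment, so the rotation determinant is always +1.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (N >= 3, not all
#'   collinear).
#' @param weights optional nonnegative weights, length N.
#' @return a `superposition_result`: list with `rotation` (3 x 3),
#'   `translation` (length 3; transformed point = `rotation %*% p +
#'   translation`), `rmsd_all`, `rmsd_kept`, `n_input`, `n_rejected`,
#'   `cycles_run`, `kept` (logical vector), `warning_flag`.
#' @export
kabsch <- function(coords_a, coords_b, weights = NULL) {
  n <- nrow(coords_a)
  if (is.null(n) || n < 3 || nrow(coords_b) != n) {
    stop("degenerate input: need at least 3 paired points", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  w <- weights / sum(weights)
  ca <- colSums(coords_a * w)
  cb <- colSums(coords_b * w)
  ac <- sweep(coords_a, 2, ca)
  bc <- sweep(coords_b, 2, cb)
  h <- t(bc * w) %*% ac
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(ca - rot %*% cb)
  moved <- apply_rigid(coords_b, rot, trans)
  r <- rmsd_coords(coords_a, moved)
  res <- list(rotation = rot, translation = trans, rmsd_all = r,
              rmsd_kept = r, n_input = n, n_rejected = 0L,
              cycles_run = 0L, kept = rep(TRUE, n), warning_flag = FALSE)
  class(res) <- "superposition_result"
  res
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(paste0("superposition_result: n_input=%d n_rejected=%d ",
                     "cycles=%d rmsd_all=%.4f rmsd_kept=%.4f%s\n"),
              x$n_input, x$n_rejected, x$cycles_run, x$rmsd_all,
              x$rmsd_kept, if (isTRUE(x$warning_flag)) " [warning]" else ""))
  invisible(x)
}

apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

#' Rigid superposition with iterative outlier rejection
#'
#' Mirrors the contract of visual-best-fit alignment tools: after an
#' initial least-squares fit, atom pairs whose post-fit distance exceeds
#' `reject_sigma` times the current retained-set RMSD are discarded and the
#' fit repeated, up to `max_cycles` cycles or until no pair is rejected.
#' Both the RMSD over the full original pairing (`rmsd_all`) and over the
#' retained pairs (`rmsd_kept`) are reported, since either may be the
#' number quoted for a comparison.
#'
#' @param ap an `atom_pairing` from [pair_atoms()].
#' @param a,b the `structure_model` objects the pairing refers to.
#' @param max_cycles maximum rejection cycles (default 5).
#' @param reject_sigma rejection multiplier on the retained RMSD
#'   (default 2).
#' @return a `superposition_result` (see [kabsch()]); `kept` marks the atom
#'   pairs retained by the final fit, and `warning_flag` is set if a
#'   rejection cycle was refused because it would leave fewer than 3 pairs.
#' @export
refine_superposition <- function(ap, a, b, max_cycles = 5,
                                 reject_sigma = 2.0) {
  xa <- coords(a, ap$row_a)
  xb <- coords(b, ap$row_b)
  n <- nrow(xa)
  kept <- rep(TRUE, n)
  fit <- kabsch(xa, xb)
  cycles <- 0L
  while (cycles < max_cycles) {
    moved <- apply_rigid(xb, fit$rotation, fit$translation)
    dist_kept <- sqrt(rowSums((xa - moved)^2))
    # floor keeps exact fits (rmsd ~ machine epsilon) from rejecting
    # perfectly matched atoms
    cutoff <- max(reject_sigma * fit$rmsd_kept, 1e-8)
    reject <- kept & dist_kept > cutoff
    if (!any(reject)) break
    if (sum(kept & !reject) < 3) {
      fit$warning_flag <- TRUE
      break
    }
    kept <- kept & !reject
    fit_new <- kabsch(xa[kept, , drop = FALSE], xb[kept, , drop = FALSE])
    fit$rotation <- fit_new$rotation
    fit$translation <- fit_new$translation
    fit$rmsd_kept <- fit_new$rmsd_all
    cycles <- cycles + 1L
  }
  moved <- apply_rigid(xb, fit$rotation, fit$translation)
  fit$rmsd_all <- rmsd_coords(xa, moved)
  if (fit$cycles_run == 0L && cycles == 0L) {
    fit$rmsd_kept <- fit$rmsd_all
  }
  fit$n_input <- n
  fit$n_rejected <- sum(!kept)
  fit$cycles_run <- cycles
  fit$kept <- kept
  class(fit) <- "superposition_result"
  fit
}

#' Apply a superposition to a whole structure model
#'
#' @param model a `structure_model`.
#' @param sr a `superposition_result`.
#' @return the transformed `structure_model` (topology unchanged).
#' @export
transform_model <- function(model, sr) {
  xyz <- apply_rigid(coords(model), sr$rotation, sr$translation)
  model$atom$x <- xyz[, 1]
  model$atom$y <- xyz[, 2]
  model$atom$z <- xyz[, 3]
  model
}

#' Summarize one or more superpositions as a report table
#'
#' @param fits named list of `superposition_result` objects.
#' @return data frame with one row per comparison (`label`, `n_input`,
#'   `n_rejected`, `cycles_run`, `rmsd_all`, `rmsd_kept`).
#' @export
superposition_report <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(label = nm, n_input = f$n_input, n_rejected = f$n_rejected,
               cycles_run = f$cycles_run, rmsd_all = f$rmsd_all,
               rmsd_kept = f$rmsd_kept, stringsAsFactors = FALSE)
  }))
}
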