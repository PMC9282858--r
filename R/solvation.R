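#' @title Residue-wise water accessibility
#' @description The mean number of water molecules within a cutoff
#'   (default 5 Angstrom) of any atom of each residue, per frame, with
#'   minimum-image distances when a box is present. A water molecule is
#'   counted once per residue per frame as soon as any of its atoms is
#'   within the cutoff of any atom of the residue.
#' @name memdyn-solvation
NULL

#' Water accessibility profile
#'
#' @param traj a `Trajectory`.
#' @param residues `Selection` naming the residues to profile (e.g. the
#'   substrate transmembrane residues).
#' @param cutoff neighbor cutoff in Angstrom (default 5).
#' @param heavy_only count only non-hydrogen atoms on both sides
#'   (default FALSE: "any atom" includes hydrogens when present).
#' @param window trailing analysis window, see [analysis_window()]; the
#'   default uses all frames.
#' @return object of class `WaterAccessibilityProfile`: data.frame with
#'   `label` and `mean_waters` (per-frame mean count per residue).
#' @export
water_accessibility <- function(traj, residues, cutoff = 5.0,
                                heavy_only = FALSE, window = 1.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  top <- traj$topology
  a <- top$atoms
  wat <- which(a$role == "water")
  res_rows <- selection_residues(top, residues)
  labs <- residue_labels(top)[res_rows]
  if (!length(wat)) {
    warning("no waters in system; all-zero profile")
    out <- data.frame(label = labs, mean_waters = 0, stringsAsFactors = FALSE)
    class(out) <- c("WaterAccessibilityProfile", "data.frame")
    return(out)
  }
  if (heavy_only) wat <- wat[toupper(a$element[wat]) != "H"]
  # water atom -> water molecule (residue) id
  wmol <- findInterval(wat, top$residues$first)
  q <- neighbor_query(cutoff)
  widx <- analysis_window(traj, window)
  acc <- matrix(0, length(widx), length(res_rows))
  for (fk in seq_along(widx)) {
    f <- traj$frames[[widx[fk]]]
    wxyz <- f$xyz[wat, , drop = FALSE]
    for (rk in seq_along(res_rows)) {
      rng <- top$residues$first[res_rows[rk]]:top$residues$last[res_rows[rk]]
      if (heavy_only) rng <- rng[toupper(a$element[rng]) != "H"]
      hit <- neighbors_within(f$xyz[rng, , drop = FALSE], wxyz, q, f$box)
      acc[fk, rk] <- length(unique(wmol[hit]))
    }
  }
  out <- data.frame(label = labs, mean_waters = colMeans(acc),
                    stringsAsFactors = FALSE)
  class(out) <- c("WaterAccessibilityProfile", "data.frame")
  out
}
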