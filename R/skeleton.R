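#' Topological skeleton (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning of a binary mask down to 8-connected
#' unit-width centrelines.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  img <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shiftMat(img, -1, 0, FALSE); p3 <- shiftMat(img, -1, 1, FALSE)
      p4 <- shiftMat(img, 0, 1, FALSE);  p5 <- shiftMat(img, 1, 1, FALSE)
      p6 <- shiftMat(img, 1, 0, FALSE);  p7 <- shiftMat(img, 1, -1, FALSE)
      p8 <- shiftMat(img, 0, -1, FALSE); p9 <- shiftMat(img, -1, -1, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- img & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- img & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

skeletonGraph <- function(skel) {
  idx <- which(skel)
  nr <- nrow(skel)
  dirs <- c(-1L, nr - 1L, nr, nr + 1L)
  drow <- c(-1L, -1L, 0L, 1L)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_along(dirs)) {
    nb <- idx + dirs[k]
    rn <- (idx - 1L) %% nr + 1L + drow[k]
    ok <- nb >= 1L & nb <= length(skel) & rn >= 1L & rn <= nr
    nb <- nb[ok]; src <- idx[ok]
    hit <- skel[nb]
    from <- c(from, match(src[hit], idx))
    to <- c(to, match(nb[hit], idx))
    w <- c(w, rep(if (drow[k] == 0L || dirs[k] == -1L) 1 else sqrt(2), sum(hit)))
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- w
  list(g = g, idx = idx, nr = nr)
}

#' Detect sprouts on a segmented vessel mask
#'
#' Skeletonises the mask; sprout candidates are skeleton pixels inside the
#' wound band.  Each 8-connected in-band component that attaches to a
#' stump trunk (skeleton pixels in the proximal or distal region) becomes
#' one sprout; its path runs from the attachment point to the tip of the
#' longest wound-ward geodesic (ties broken towards the leftmost tip, so
#' detection is deterministic), and its side is the region of the trunk it
#' attaches to.  Branches shorter than `minLengthUm` are discarded.
#'
#' @param mask logical vessel mask from [segmentVessels()].
#' @param roiSet a [RoiSet-class] providing the region masks.
#' @param minLengthUm detection floor (µm), default 10.
#' @return data.frame with one row per sprout: `sprout_id`, `side`,
#'   `length_um`, `tip_row`, `tip_col` (0-based pixels) and a list column
#'   `skeleton_path` of (row, col) pixel polylines.
#' @export
detectSprouts <- function(mask, roiSet, minLengthUm = 10) {
  regions <- regionMasks(roiSet)
  stopIfNot(all(c("proximal", "distal", "wound") %in% names(regions)),
            "configuration error: missing region masks")
  ps <- pixelSize(roiSet)
  skel <- skeletonize(mask)
  band <- skel & regions$wound
  out <- emptySproutMeasurements()
  if (!any(band)) return(out)
  lab <- labelComponents(band)
  sg <- skeletonGraph(skel)
  nr <- sg$nr
  trunkProx <- which(skel & regions$proximal)
  trunkDist <- which(skel & regions$distal)
  neighbours <- function(ii) {
    r <- (ii - 1L) %% nr + 1L
    offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
    dr <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
    nb <- rep(ii, each = 8L) + offs
    rn <- rep(r, each = 8L) + dr
    nb[nb >= 1L & nb <= length(skel) & rn >= 1L & rn <= nr]
  }
  recs <- list()
  paths <- list()
  for (comp in seq_len(max(lab))) {
    cells <- which(lab == comp)
    nbs <- unique(neighbours(cells))
    side <- if (any(nbs %in% trunkDist)) "distal"
      else if (any(nbs %in% trunkProx)) "proximal"
      else NA_character_
    if (is.na(side)) next                     # floating branch: not attached
    trunk <- if (side == "distal") trunkDist else trunkProx
    entry <- cells[vapply(cells, function(ci) any(neighbours(ci) %in% trunk), TRUE)]
    if (!length(entry)) entry <- cells[1]
    vEntry <- match(entry, sg$idx)
    dmat <- igraph::distances(sg$g, v = vEntry, to = match(cells, sg$idx))
    dmin <- apply(dmat, 2, min)
    reach <- is.finite(dmin)
    if (!any(reach)) next
    ## tip = farthest in-band pixel; tie -> leftmost column
    cand <- which(reach)
    best <- cand[order(-dmin[cand], (cells[cand] - 1L) %/% nr)][1]
    lenPx <- dmin[best]
    if (lenPx * ps < minLengthUm) next
    src <- vEntry[which.min(dmat[, best])]
    pathV <- igraph::shortest_paths(sg$g, from = src,
                                    to = match(cells[best], sg$idx))$vpath[[1]]
    cellPath <- sg$idx[as.integer(pathV)]
    coords <- cbind(row = (cellPath - 1L) %% nr, col = (cellPath - 1L) %/% nr)
    ## measure from the parent wall to the segmented tip: thinning retracts
    ## skeleton endpoints inside the mask, so (i) extend the root to the
    ## wall row (the band-adjacent stump row the trunk terminates in) and
    ## (ii) walk the tip forward through the mask along the branch
    ## direction
    bandRows <- which(rowSums(regions$wound) > 0)
    edge0 <- if (side == "distal") max(bandRows) else min(bandRows) - 2L
    rootGapPx <- abs(edge0 - coords[1, "row"])
    tipExt <- 0L
    dir <- c(0, 0)
    if (nrow(coords) >= 2L) {
      dir <- sign(coords[nrow(coords), ] - coords[nrow(coords) - 1L, ])
      pos <- coords[nrow(coords), ]
      while (tipExt < 4L) {
        pos <- pos + dir
        if (any(pos < 0) || pos[1] >= nrow(mask) || pos[2] >= ncol(mask)) break
        if (!mask[pos[1] + 1L, pos[2] + 1L]) break
        tipExt <- tipExt + 1L
      }
    }
    lenPx <- lenPx + rootGapPx + tipExt * sqrt(sum(dir^2))
    recs[[length(recs) + 1L]] <- data.frame(
      sprout_id = sprintf("det%03d", length(recs) + 1L), side = side,
      length_um = lenPx * ps,
      tip_row = (cells[best] - 1L) %% nr,
      tip_col = (cells[best] - 1L) %/% nr,
      stringsAsFactors = FALSE)
    paths[[length(paths) + 1L]] <- coords
  }
  if (!length(recs)) return(out)
  out <- do.call(rbind, recs)
  out$skeleton_path <- paths
  out
}

emptySproutMeasurements <- function() {
  out <- data.frame(sprout_id = character(), side = character(),
                    length_um = numeric(), tip_row = numeric(),
                    tip_col = numeric(), stringsAsFactors = FALSE)
  out$skeleton_path <- list()
  out
}

#' Geodesic length of a skeleton path
#'
#' Sum of Euclidean inter-vertex steps times the pixel size; a single-point
#' path has length zero (with a warning).
#'
#' @param path matrix of (row, col) pixel vertices.
#' @param pixelSizeUm µm per pixel.
#' @return length in µm.
#' @export
measureLength <- function(path, pixelSizeUm) {
  stopIfNot(is.matrix(path) && nrow(path) >= 1, "skeleton path is empty")
  if (nrow(path) == 1L) {
    warning("single-point path has zero length")
    return(0)
  }
  sum(sqrt(rowSums(diff(path)^2))) * pixelSizeUm
}

#' Summarise sprout measurements into cohort rows
#'
#' Counts per side and mean length per side for one (animal, session).
#' Sessions without sprouts yield a count of 0 and a *missing* mean length
#' (never 0), so that length models ignore them.
#'
#' @param measurements data.frame from [detectSprouts()] (or ground truth
#'   with columns `side`, `length_um`).
#' @param animalId animal identifier.
#' @param dpt session day.
#' @return tidy data.frame (`animal_id`, `dpt`, `metric`, `side`, `value`).
#' @export
summarizeSprouts <- function(measurements, animalId, dpt) {
  rows <- lapply(c("proximal", "distal"), function(sd) {
    sel <- measurements$side == sd
    data.frame(animal_id = animalId, dpt = dpt,
               metric = c("sprout_count", "mean_length_um"), side = sd,
               value = c(sum(sel),
                         if (any(sel)) mean(measurements$length_um[sel]) else NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
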