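#' Scene geometry parameters
#'
#' Defaults describe the imaging configuration of the emulated experiment:
#' a 1 x 1 mm field of view, a wound band crossing it horizontally, arterial
#' stumps terminating on the band edges and veins running alongside.
#' `woundGapUm` is the functional bridging distance: the distance a sprout
#' must cover into the wound before it can connect to the proximal stump or
#' to other perfused vessels in the vicinity.
#'
#' @param fovUm field of view (µm), length 1 or 2.
#' @param woundWidthUm width of the wound band (µm).
#' @param woundGapUm functional bridging distance (µm).
#' @param arteryRadiusUm arterial stump radius (µm).
#' @param veinRadiusUm vein radius (µm).
#' @param wallArmUm half-length of the stump end-wall running along the
#'   wound edge, from which sprouts emerge (µm).
#' @return a named list of scene parameters.
#' @export
sceneParams <- function(fovUm = c(1000, 1000), woundWidthUm = 300,
                        woundGapUm = 30, arteryRadiusUm = 8,
                        veinRadiusUm = 12, wallArmUm = 180) {
  if (length(fovUm) == 1L) fovUm <- rep(fovUm, 2L)
  list(fovUm = fovUm, woundWidthUm = woundWidthUm, woundGapUm = woundGapUm,
       arteryRadiusUm = arteryRadiusUm, veinRadiusUm = veinRadiusUm,
       wallArmUm = wallArmUm)
}

#' Build a synthetic vascular scene
#'
#' Constructs `nArteries` transsected arteries: each contributes a proximal
#' stump (terminating on the proximal wound edge) and a distal stump
#' (terminating on the distal edge), with a short end-wall arm along the
#' edge representing the cut vessel end.  One vein is placed alongside each
#' artery on both sides, within anastomosis reach of the stump, and
#' candidate anastomosis sites are recorded.  Deterministic for a given
#' seed.
#'
#' @param seed integer RNG seed.
#' @param nArteries number of transsected arteries (>= 1).
#' @param params scene parameters from [sceneParams()].
#' @return a [VascularScene-class] object.
#' @examples
#' sc <- makeScene(42, nArteries = 2)
#' length(stumps(sc, "distal"))
#' @export
makeScene <- function(seed, nArteries = 2, params = sceneParams()) {
  stopIfNot(nArteries >= 1, "nArteries must be >= 1")
  fov <- params$fovUm
  if (params$woundWidthUm >= fov[2])
    stop("configuration error: wound band (", params$woundWidthUm,
         " um) does not fit the FOV (", fov[2], " um)")
  yMid <- fov[2] / 2
  band <- c(yMid - params$woundWidthUm / 2, yMid + params$woundWidthUm / 2)
  withSeed(seed, {
    ## artery x-positions spread over the central FOV, jittered
    x0 <- fov[1] * (seq_len(nArteries) / (nArteries + 1)) +
      runif(nArteries, -0.03, 0.03) * fov[1]
    arm <- params$wallArmUm
    mkStump <- function(i, side) {
      x <- x0[i]
      ## trunk ends at the terminal on the wound edge; the thin cut-wall
      ## arm runs along the edge, set back ~8 µm into the stump's own
      ## territory so in-band skeleton branches (sprouts) never merge
      ## through it
      if (side == "proximal") {
        yEdge <- band[1]
        path <- rbind(c(x, 0), c(x + runif(1, -30, 30), yEdge * 0.5),
                      c(x, yEdge))
        armSeg <- rbind(c(x, yEdge - 8), c(min(x + arm, fov[1] - 5), yEdge - 8))
      } else {
        yEdge <- band[2]
        path <- rbind(c(x, fov[2]), c(x + runif(1, -30, 30), (yEdge + fov[2]) / 2),
                      c(x, yEdge))
        armSeg <- rbind(c(x, yEdge + 8), c(min(x + arm, fov[1] - 5), yEdge + 8))
      }
      list(id = sprintf("art%d_%s", i, substr(side, 1, 4)), path = path,
           radiusUm = params$arteryRadiusUm, terminalUm = c(x, yEdge),
           arm = armSeg, armRadiusUm = 4)
    }
    mkVein <- function(i, side) {
      x <- min(x0[i] + 60 + runif(1, -10, 10), fov[1] - 5)
      if (side == "proximal")
        path <- rbind(c(x, 0), c(x, band[1]))
      else
        path <- rbind(c(x, fov[2]), c(x, band[2]))
      list(id = sprintf("vein%d_%s", i, substr(side, 1, 4)), path = path,
           radiusUm = params$veinRadiusUm)
    }
    prox <- lapply(seq_len(nArteries), mkStump, side = "proximal")
    dist <- lapply(seq_len(nArteries), mkStump, side = "distal")
    vns <- c(lapply(seq_len(nArteries), mkVein, side = "proximal"),
             lapply(seq_len(nArteries), mkVein, side = "distal"))
    sites <- do.call(rbind, lapply(seq_len(nArteries), function(i) {
      data.frame(
        stump_id = c(prox[[i]]$id, dist[[i]]$id),
        vein_id = c(vns[[i]]$id, vns[[nArteries + i]]$id),
        x_um = c(mean(c(x0[i], vns[[i]]$path[1, 1])),
                 mean(c(x0[i], vns[[nArteries + i]]$path[1, 1]))),
        y_um = c(band[1] - 40, band[2] + 40))
    }))
    new("VascularScene", sceneId = sprintf("scene_seed%d", as.integer(seed)),
        fovUm = fov, woundBand = band, woundGapUm = params$woundGapUm,
        proximalStumps = prox, distalStumps = dist, veins = vns,
        anastomosisSites = sites, rngSeed = as.integer(seed))
  })
}
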