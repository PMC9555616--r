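#' @include AllClasses.R
NULL

# spherical (inclination from vertex, azimuth from +x ccw; degrees) -> xyz mm
.sph2xyz <- function(incl, az, radius) {
  i <- incl * pi / 180; a <- az * pi / 180
  cbind(x = radius * sin(i) * cos(a),
        y = radius * sin(i) * sin(a),
        z = radius * cos(i))
}

#' Construct the fixed motor-cortex probe layout
#'
#' Sixteen regular channels (30 mm source-detector separation) in three
#' regions of interest -- SMA around the vertex, M1 left around C3 and M1
#' right around C4 -- plus four channels outside any ROI, and eight
#' short-distance channels (8 mm) co-located with the optode clusters.
#' Channel midpoints sit on a template scalp sphere at 10-5-like coordinates;
#' the function is deterministic.
#'
#' @param headRadius scalp sphere radius in mm.
#' @return a [ProbeLayout-class].
#' @examples
#' layout <- makeProbeLayout()
#' layout
#' @export
makeProbeLayout <- function(headRadius = 87.5) {
  # azimuth convention: 90 deg = anterior, 180 deg = left, 0 deg = right
  reg <- data.frame(
    channel = 1:16,
    source   = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 8),
    detector = c(1, 2, 1, 2, 3, 4, 3, 4, 5, 6, 5, 6, 7, 8, 7, 8),
    incl = c(12, 18, 18, 24,      # SMA cluster (vertex, slightly anterior)
             35, 40, 45, 40,      # M1 left cluster (around C3)
             35, 40, 45, 40,      # M1 right cluster (around C4)
             35, 35, 55, 55),     # peripheral, outside the ROIs
    az   = c(90, 75, 105, 90,
             170, 180, 170, 160,
             10, 0, 10, 20,
             235, 305, 190, 350),
    roi = c(rep("SMA", 4), rep("M1_LEFT", 4), rep("M1_RIGHT", 4),
            rep("NONE", 4)),
    distance = 30)
  # SDCs sit at the source optodes, offset from the channel midpoints
  sdc <- data.frame(
    channel = 1:8,
    source   = c(1, 3, 3, 4, 2, 5, 6, 6),
    detector = rep(9L, 8),
    incl = c(20, 30, 50, 34, 20, 30, 34, 50),
    az   = c(60, 168, 165, 186, 120, 12, 354, 15),
    roi = "NONE",
    distance = 8)
  reg$type <- "regular"; sdc$type <- "sdc"
  ch <- rbind(reg, sdc)
  xyz <- .sph2xyz(ch$incl, ch$az, headRadius)
  ch <- cbind(ch[c("channel", "type", "source", "detector", "roi",
                   "distance")], as.data.frame(xyz))
  rownames(ch) <- paste0(ifelse(ch$type == "sdc", "S", "R"), ch$channel)
  new("ProbeLayout", channels = ch[c("channel", "type", "source", "detector",
                                     "x", "y", "z", "roi", "distance")],
      headRadius = headRadius)
}

#' Pairwise distances between channel midpoints
#'
#' @param layout a [ProbeLayout-class].
#' @param type distance type: straight-line "euclidean" in mm or
#'   "angular" great-circle distance in degrees on the layout sphere.
#' @param channels subset of layout rows ("regular", "sdc" or "all").
#' @return symmetric distance matrix.
#' @export
channelDistances <- function(layout, type = c("euclidean", "angular"),
                             channels = c("all", "regular", "sdc")) {
  type <- match.arg(type); channels <- match.arg(channels)
  ch <- layout@channels
  if (channels != "all") ch <- ch[ch$type == channels, ]
  P <- as.matrix(ch[, c("x", "y", "z")])
  if (type == "euclidean") {
    D <- as.matrix(stats::dist(P))
  } else {
    U <- P / layout@headRadius
    cosang <- pmin(pmax(tcrossprod(U), -1), 1)
    D <- acos(cosang) * 180 / pi
    diag(D) <- 0
  }
  dimnames(D) <- list(rownames(ch), rownames(ch))
  D
}

#' Nearest short-distance channel for every regular channel
#'
#' Euclidean nearest SDC; ties broken towards the lowest SDC id. Used as the
#' default reference mapping of the short separation regression.
#'
#' @param layout a [ProbeLayout-class].
#' @param exclude SDC ids to skip (e.g. pruned SDCs); the next-nearest
#'   remaining SDC is used instead.
#' @return integer vector of SDC ids, named by regular channel id.
#' @export
nearestSDC <- function(layout, exclude = integer()) {
  ch <- layout@channels
  reg <- ch[ch$type == "regular", ]
  sdc <- ch[ch$type == "sdc", ]
  sdc <- sdc[!(sdc$channel %in% exclude), ]
  if (nrow(sdc) == 0L) stop("no usable SDCs remain")
  out <- integer(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    d <- sqrt((sdc$x - reg$x[i])^2 + (sdc$y - reg$y[i])^2 +
              (sdc$z - reg$z[i])^2)
    # ties (within numerical noise) resolve to the lowest SDC id
    cands <- sdc$channel[d <= min(d) + 1e-9]
    out[i] <- min(cands)
  }
  names(out) <- reg$channel
  out
}

# row indices of a FnirsSeries for a channel type
.rowsOfType <- function(x, type) which(rowData(x)$type == type)

# row index for (type, channel id)
.rowOfChannel <- function(x, channel, type = "regular") {
  which(rowData(x)$type == type & rowData(x)$channel == channel)
}
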