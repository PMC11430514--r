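#' The 19-channel 10-20 montage
#'
#' Standard 19-electrode subset of the international 10-20 system, in the
#' conventional left-to-right, anterior-to-posterior order.
#'
#' @return character vector of 19 channel labels
#' @export
tenTwentyLabels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4",
    "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

.tenTwentyPositions <- function() {
  deg <- function(a) a * pi / 180
  ring <- function(a) 0.5 * c(cos(deg(a)), sin(deg(a)))
  pos <- rbind(
    Fp1 = ring(108), Fp2 = ring(72),
    F7 = ring(144), F8 = ring(36),
    T3 = ring(180), T4 = ring(0),
    T5 = ring(216), T6 = ring(-36),
    O1 = ring(252), O2 = ring(288),
    Fz = c(0, 0.25), Cz = c(0, 0), Pz = c(0, -0.25),
    C3 = c(-0.25, 0), C4 = c(0.25, 0)
  )
  pos <- rbind(pos,
    F3 = (pos["F7", ] + pos["Fz", ]) / 2,
    F4 = (pos["F8", ] + pos["Fz", ]) / 2,
    P3 = (pos["T5", ] + pos["Pz", ]) / 2,
    P4 = (pos["T6", ] + pos["Pz", ]) / 2
  )
  pos <- pos[tenTwentyLabels(), ]
  colnames(pos) <- c("x", "y")
  pos
}

#' Build the spatial adjacency graph of the 10-20 montage
#'
#' Electrode coordinates are the standard 2-D projection with the head scaled
#' to unit diameter (nose up, right ear at positive x). Two channels are
#' neighbors when their Euclidean distance is at most `threshold`; the
#' default of 0.35 connects each electrode to its nearest ring of neighbors
#' and nothing further.
#'
#' @param labels channel labels; default the 19-channel 10-20 set.
#' @param threshold neighbor distance cutoff in head-diameter units.
#' @param positions optional replacement coordinate matrix (rownames =
#'   labels) for non-standard montages.
#' @return a [MontageGraph-class]
#' @examples
#' m <- standardMontage()
#' neighborsOf(m, "Cz")
#' @export
standardMontage <- function(labels = tenTwentyLabels(), threshold = 0.35,
                            positions = NULL) {
  if (is.null(positions)) {
    all <- .tenTwentyPositions()
    bad <- setdiff(labels, rownames(all))
    if (length(bad))
      stop("no standard position for channel(s): ", paste(bad, collapse = ", "))
    positions <- all[labels, , drop = FALSE]
  }
  d <- as.matrix(stats::dist(positions))
  adj <- d <= threshold
  diag(adj) <- FALSE
  new("MontageGraph", positions = positions, adjacency = adj)
}

#' Neighbors of a channel in a montage graph
#' @param montage a [MontageGraph-class]
#' @param channel channel label
#' @return character vector of neighboring channel labels
#' @export
neighborsOf <- function(montage, channel) {
  stopifnot(channel %in% rownames(montage@adjacency))
  names(which(montage@adjacency[channel, ]))
}

#' Electrode coordinates of a montage graph
#' @param montage a [MontageGraph-class]
#' @return channel x 2 coordinate matrix
#' @export
montagePositions <- function(montage) montage@positions
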