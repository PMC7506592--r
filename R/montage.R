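#' Electrode montage
#'
#' A montage describes the recording geometry: ordered channel labels, unit
#' sphere positions (x towards the right ear, y towards the nasion, z towards
#' the vertex), a symmetric neighbour map used for bad-channel interpolation,
#' and a role per channel (`scalp`, `vertical-ocular`, `horizontal-ocular`).
#' The vertex reference Cz and the lateral posterior sites P7 (text-specific)
#' and P8 (face-specific) are always present.
#'
#' @name montage
NULL

# canonical 10-20-ish unit positions for the named scalp subset; order matters:
# build_montage() fills the montage from the top of this table.
.named_positions <- function() {
  pos <- rbind(
    Cz  = c(0, 0, 1),
    P7  = c(-0.81, -0.59, 0.00),
    P8  = c(0.81, -0.59, 0.00),
    Fp1 = c(-0.31, 0.95, 0.05),
    Fp2 = c(0.31, 0.95, 0.05),
    F7  = c(-0.81, 0.59, 0.00),
    F8  = c(0.81, 0.59, 0.00),
    F3  = c(-0.55, 0.67, 0.50),
    F4  = c(0.55, 0.67, 0.50),
    C3  = c(-0.71, 0.00, 0.71),
    C4  = c(0.71, 0.00, 0.71),
    P3  = c(-0.55, -0.67, 0.50),
    P4  = c(0.55, -0.67, 0.50),
    Oz  = c(0.00, -0.99, 0.10),
    O1  = c(-0.31, -0.95, 0.05),
    O2  = c(0.31, -0.95, 0.05),
    T7  = c(-0.99, 0.00, 0.10),
    T8  = c(0.99, 0.00, 0.10),
    Pz  = c(0.00, -0.71, 0.71),
    Fz  = c(0.00, 0.71, 0.71)
  )
  sweep(pos, 1, sqrt(rowSums(pos^2)), "/")
}

# deterministic Fibonacci lattice on the upper hemisphere for extra channels
.lattice_positions <- function(n) {
  if (n <= 0) return(matrix(numeric(0), ncol = 3))
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n)
  z <- 0.05 + 0.9 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- 2 * pi * i / golden
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Build a deterministic montage
#'
#' Constructs a montage with `n_channels` channels: `n_channels - 2` scalp
#' channels (always including Cz, P7 and P8, drawn first from canonical
#' 10-20 positions, then from a deterministic spherical lattice) plus one
#' vertical-ocular (VEOG) and one horizontal-ocular (HEOG) channel.
#' Neighbours are the symmetrised 3-nearest scalp channels, so every scalp
#' channel has at least three neighbours.
#'
#' @param n_channels Total channel count, at least 16.
#' @return An object of class `erp_montage`: list with `channel_labels`,
#'   `positions` (channels x 3 matrix of unit vectors), `neighbor_map`
#'   (named list of character vectors) and `roles` (named character vector).
#' @examples
#' m <- build_montage(16)
#' m$roles[c("Cz", "VEOG")]
#' @export
build_montage <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 16) {
    stop("`n_channels` must be a single count >= 16", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  n_scalp <- n_channels - 2L

  named <- .named_positions()
  if (n_scalp <= nrow(named)) {
    scalp_pos <- named[seq_len(n_scalp), , drop = FALSE]
    scalp_lab <- rownames(named)[seq_len(n_scalp)]
  } else {
    extra <- .lattice_positions(n_scalp - nrow(named))
    extra <- sweep(extra, 1, sqrt(rowSums(extra^2)), "/")
    scalp_pos <- rbind(named, extra)
    scalp_lab <- c(rownames(named),
                   sprintf("E%02d", nrow(named) + seq_len(nrow(extra))))
  }

  ocular_pos <- rbind(
    VEOG = c(0.13, 0.97, -0.20),
    HEOG = c(0.93, 0.36, -0.10)
  )
  ocular_pos <- sweep(ocular_pos, 1, sqrt(rowSums(ocular_pos^2)), "/")

  labels <- c(scalp_lab, rownames(ocular_pos))
  positions <- rbind(scalp_pos, ocular_pos)
  rownames(positions) <- labels

  roles <- c(rep("scalp", n_scalp), "vertical-ocular", "horizontal-ocular")
  names(roles) <- labels

  # symmetrised 3-NN among scalp channels only
  d <- as.matrix(stats::dist(scalp_pos))
  diag(d) <- Inf
  nb <- lapply(seq_len(n_scalp), function(i) {
    scalp_lab[order(d[i, ])[1:3]]
  })
  names(nb) <- scalp_lab
  for (i in seq_len(n_scalp)) {
    for (j in nb[[i]]) {
      if (!(scalp_lab[i] %in% nb[[j]])) {
        nb[[j]] <- c(nb[[j]], scalp_lab[i])
      }
    }
  }
  nb[rownames(ocular_pos)] <- list(character(0), character(0))

  structure(
    list(channel_labels = labels, positions = positions,
         neighbor_map = nb, roles = roles),
    class = "erp_montage"
  )
}

#' @export
print.erp_montage <- function(x, ...) {
  cat(sprintf("<erp_montage> %d channels (%d scalp, %d ocular)\n",
              length(x$channel_labels), sum(x$roles == "scalp"),
              sum(x$roles != "scalp")))
  invisible(x)
}

#' Channels of a given montage role
#' @param montage An `erp_montage`.
#' @param role One of `"scalp"`, `"vertical-ocular"`, `"horizontal-ocular"`.
#' @return Character vector of channel labels.
#' @export
montage_channels <- function(montage, role = "scalp") {
  stopifnot(inherits(montage, "erp_montage"))
  names(montage$roles)[montage$roles == role]
}

#' Write / read a montage as JSON
#'
#' @param montage An `erp_montage`.
#' @param path File path.
#' @return `write_montage_json` returns `path` invisibly; `read_montage_json`
#'   returns the montage.
#' @export
write_montage_json <- function(montage, path) {
  stopifnot(inherits(montage, "erp_montage"))
  obj <- list(
    channel_labels = montage$channel_labels,
    positions = unname(split(montage$positions, row(montage$positions))),
    neighbor_map = montage$neighbor_map,
    roles = as.list(montage$roles)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  positions <- if (is.matrix(obj$positions)) obj$positions else
    do.call(rbind, obj$positions)
  rownames(positions) <- obj$channel_labels
  nb <- lapply(obj$neighbor_map, function(v) as.character(unlist(v)))
  structure(
    list(channel_labels = obj$channel_labels,
         positions = positions,
         neighbor_map = nb,
         roles = unlist(obj$roles)),
    class = "erp_montage"
  )
}

validate_montage <- function(montage) {
  stopifnot(inherits(montage, "erp_montage"))
  lab <- montage$channel_labels
  if (anyDuplicated(lab)) stop("montage labels must be unique", call. = FALSE)
  if (!all(c("P7", "P8", "Cz") %in% lab)) {
    stop("montage must contain P7, P8 and Cz", call. = FALSE)
  }
  norms <- sqrt(rowSums(montage$positions^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("montage positions must have unit norm", call. = FALSE)
  }
  scalp <- montage_channels(montage, "scalp")
  nn <- vapply(montage$neighbor_map[scalp], length, integer(1))
  if (any(nn < 2)) stop("every scalp channel needs >= 2 neighbors", call. = FALSE)
  invisible(montage)
}
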