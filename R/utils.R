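# Internal helpers shared across modules.

#' Evaluate code with a local random seed
#'
#' All stochastic operations in the package take an explicit integer seed and
#' restore the caller's random state afterwards, so nothing depends on (or
#' perturbs) the global RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed from a master seed plus labels
# (subject ids, run ids, stage names). Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- list(seed, ...)
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else as.numeric(p)
    h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  }
  as.integer(h %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 6- or 26-neighbourhood offsets as an m x 3 integer matrix, ordered by
# increasing linear offset so that ties resolve to the lowest linear index.
neighbor_offsets <- function(connectivity = 6) {
  if (connectivity == 6) {
    off <- rbind(c(0, 0, -1), c(0, -1, 0), c(-1, 0, 0),
                 c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    off <- off[order(off[, 3], off[, 2], off[, 1]), , drop = FALSE]
  } else {
    stop("connectivity must be 6 or 26")
  }
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  off
}

# For each voxel in `idx` (linear indices into an array of dims `dims`),
# return an n x m matrix of neighbour linear indices (NA where the neighbour
# falls outside the grid). Columns follow neighbor_offsets() order.
neighbor_index_matrix <- function(idx, dims, connectivity = 6) {
  off <- neighbor_offsets(connectivity)
  n <- length(idx)
  ijk <- arrayInd(idx, dims)
  out <- matrix(NA_integer_, n, nrow(off))
  for (m in seq_len(nrow(off))) {
    ni <- ijk[, 1] + off[m, 1]
    nj <- ijk[, 2] + off[m, 2]
    nk <- ijk[, 3] + off[m, 3]
    ok <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2] & nk >= 1L & nk <= dims[3]
    lin <- ni + (nj - 1L) * dims[1] + (nk - 1L) * dims[1] * dims[2]
    lin[!ok] <- NA_integer_
    out[, m] <- lin
  }
  out
}

#' Label connected components of a binary volume
#'
#' Flood-fill labelling of the `TRUE` voxels of a 3-D logical array. Component
#' labels are assigned in order of each component's smallest linear index, so
#' the labelling is deterministic.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3)
  labels <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  nbr <- neighbor_index_matrix(idx, dims, connectivity)
  pos <- integer(prod(dims))        # linear index -> row in idx/nbr
  pos[idx] <- seq_along(idx)
  inmask <- logical(prod(dims))
  inmask[idx] <- TRUE
  current <- 0L
  for (start in idx) {
    if (labels[start] > 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      nb <- nbr[pos[v], ]
      nb <- nb[!is.na(nb)]
      nb <- nb[inmask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- current
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

# Largest 6-connected component size among voxels of `mask` (logical array).
max_component_size <- function(mask, connectivity = 6) {
  if (!any(mask)) return(0L)
  labs <- label_components(mask, connectivity)
  max(tabulate(labs[labs > 0L]))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}
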