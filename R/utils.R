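# Internal helpers shared across modules.

stop_gliopred <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "gliopred_error", "error"),
                      call = call))
}

warn_gliopred <- function(message, class) {
  warning(warningCondition(message, class = c(class, "gliopred_warning",
                                              "warning")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Trapezoidal integral of y over t (both numeric vectors, t increasing).
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(t)) / 2
}

# Running trapezoidal integral; element i is the integral of y over t[1..i].
cumtrapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-1L] + y[-n]) * diff(t) / 2))
}

# 6-connected component labelling of a logical 3D array. Returns an integer
# array, 0 outside the mask, components numbered from 1 in decreasing size.
label_components_3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  labels <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)

  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  coord <- arrayInd(idx, dims)
  in_mask <- array(FALSE, dims)
  in_mask[idx] <- TRUE

  current <- 0L
  sizes <- integer(0)
  for (seed in idx) {
    if (labels[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    labels[seed] <- current
    count <- 0L
    while (length(queue) > 0L) {
      count <- count + length(queue)
      ci <- arrayInd(queue, dims)
      nbrs <- rbind(
        ci + matrix(c( 1L, 0L, 0L), nrow(ci), 3L, byrow = TRUE),
        ci + matrix(c(-1L, 0L, 0L), nrow(ci), 3L, byrow = TRUE),
        ci + matrix(c(0L,  1L, 0L), nrow(ci), 3L, byrow = TRUE),
        ci + matrix(c(0L, -1L, 0L), nrow(ci), 3L, byrow = TRUE),
        ci + matrix(c(0L, 0L,  1L), nrow(ci), 3L, byrow = TRUE),
        ci + matrix(c(0L, 0L, -1L), nrow(ci), 3L, byrow = TRUE))
      keep <- nbrs[, 1L] >= 1L & nbrs[, 1L] <= nx &
              nbrs[, 2L] >= 1L & nbrs[, 2L] <= ny &
              nbrs[, 3L] >= 1L & nbrs[, 3L] <= nz
      nbrs <- nbrs[keep, , drop = FALSE]
      lin <- nbrs[, 1L] + nx * (nbrs[, 2L] - 1L) + nx * ny * (nbrs[, 3L] - 1L)
      lin <- unique(lin[in_mask[lin] & labels[lin] == 0L])
      labels[lin] <- current
      queue <- lin
    }
    sizes <- c(sizes, count)
  }
  # renumber so component 1 is the largest
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(current)
  remap[ord] <- seq_len(current)
  nz_idx <- labels != 0L
  labels[nz_idx] <- remap[labels[nz_idx]]
  labels
}

# Percentile with the linear-interpolation (type 7) convention used for all
# lesion features; alternative "mean tail" convention kept selectable.
lesion_percentile <- function(x, p, convention = c("interpolated", "tail_mean")) {
  convention <- match.arg(convention)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (convention == "interpolated") {
    unname(stats::quantile(x, probs = p, type = 7))
  } else if (p >= 0.5) {
    q <- unname(stats::quantile(x, probs = p, type = 7))
    mean(x[x >= q])
  } else {
    q <- unname(stats::quantile(x, probs = p, type = 7))
    mean(x[x <= q])
  }
}
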