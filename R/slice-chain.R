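# Discrete catheter-content model: the shared dead volume + catheter lumen is
# an ordered chain of volume slices, each carrying per-drug volume fractions.
# Fluid entering at the mixing point pushes new slices onto the proximal end;
# the same volume leaves the distal (patient) end. This shift register is the
# time-domain realization of a Z-transform description of the catheter
# contents. Plug advection over the chain is exact: pushed slices take
# whatever volume a step moves, so the spatial resolution of a composition
# front is the per-step advected volume (bounded by the slice volume used for
# the initial fill).

#' Slice chain: discrete contents of the shared volume
#'
#' @param total_volume_ml shared volume represented by the chain (mL).
#' @param fractions named numeric vector of initial per-drug volume
#'   fractions; must sum to 1.
#' @param slice_volume_ml target volume of the initial slices; the chain is
#'   filled with `ceiling(total/slice)` equal slices.
#' @return A `slice_chain` object: list with `volumes_ml` (distal end first)
#'   and `fractions` (drugs x slices matrix).
#' @examples
#' slice_chain(0.5, c(drug_A = 0.8, drug_B = 0.2), 0.05)
#' @export
slice_chain <- function(total_volume_ml, fractions, slice_volume_ml = total_volume_ml / 200) {
  stopifnot_positive(total_volume_ml = total_volume_ml,
                     slice_volume_ml = slice_volume_ml)
  check_fractions(fractions)
  n <- max(1L, ceiling(total_volume_ml / slice_volume_ml))
  vols <- rep(total_volume_ml / n, n)
  fr <- matrix(rep(as.numeric(fractions), n), ncol = n,
               dimnames = list(names(fractions), NULL))
  structure(list(volumes_ml = vols, fractions = fr, drugs = names(fractions)),
            class = "slice_chain")
}

check_fractions <- function(fractions, tol = 1e-12) {
  if (is.null(names(fractions)) || any(names(fractions) == "")) {
    abort("`fractions` must be a named numeric vector (names are drug labels).",
          class = "infusim_invalid_parameter")
  }
  if (any(fractions < -tol) || abs(sum(fractions) - 1) > 1e-9) {
    abort("Drug volume fractions must be non-negative and sum to 1.",
          class = "infusim_invalid_parameter")
  }
  invisible(TRUE)
}

#' @export
print.slice_chain <- function(x, ...) {
  cat(sprintf("<slice_chain> %d slices, %.4g mL total, drugs: %s\n",
              length(x$volumes_ml), sum(x$volumes_ml),
              paste(x$drugs, collapse = ", ")))
  invisible(x)
}

# ---- mutable deque used by the simulation engine --------------------------
# Environment-based so the per-step push/pop is O(1) amortized. Index `lo`
# is the distal slice (next to leave), `hi` the proximal (most recent entry).

new_deque <- function(n_drugs, capacity = 1024L) {
  d <- new.env(parent = emptyenv())
  d$vol <- numeric(capacity)
  d$frac <- matrix(0, n_drugs, capacity)
  d$lo <- 1L
  d$hi <- 0L
  d
}

dq_from_chain <- function(chain, capacity_hint = 1024L) {
  n <- length(chain$volumes_ml)
  d <- new_deque(nrow(chain$fractions), max(capacity_hint, 2L * n))
  d$vol[seq_len(n)] <- chain$volumes_ml
  d$frac[, seq_len(n)] <- chain$fractions
  d$hi <- n
  d
}

dq_to_chain <- function(d, drugs) {
  idx <- seq.int(d$lo, d$hi)
  structure(list(volumes_ml = d$vol[idx],
                 fractions = matrix(d$frac[, idx], nrow = length(drugs),
                                    dimnames = list(drugs, NULL)),
                 drugs = drugs),
            class = "slice_chain")
}

dq_grow <- function(d) {
  cap <- length(d$vol)
  # compact first if the dead zone below `lo` is large
  if (d$lo > cap %/% 2L) {
    n <- d$hi - d$lo + 1L
    d$vol[seq_len(n)] <- d$vol[seq.int(d$lo, d$hi)]
    d$frac[, seq_len(n)] <- d$frac[, seq.int(d$lo, d$hi)]
    d$lo <- 1L
    d$hi <- n
  } else {
    d$vol <- c(d$vol, numeric(cap))
    d$frac <- cbind(d$frac, matrix(0, nrow(d$frac), cap))
  }
  invisible(d)
}

dq_push <- function(d, dv, frac) {
  if (d$hi == length(d$vol)) dq_grow(d)
  d$hi <- d$hi + 1L
  d$vol[d$hi] <- dv
  d$frac[, d$hi] <- frac
  invisible(d)
}

# remove `dv` from the distal end; returns the volume-weighted mixture
# fractions of what left.
dq_pop <- function(d, dv) {
  acc <- numeric(nrow(d$frac))
  remaining <- dv
  while (remaining > 0 && d$lo <= d$hi) {
    v <- d$vol[d$lo]
    if (v <= remaining) {
      acc <- acc + v * d$frac[, d$lo]
      remaining <- remaining - v
      d$lo <- d$lo + 1L
    } else {
      acc <- acc + remaining * d$frac[, d$lo]
      d$vol[d$lo] <- v - remaining
      remaining <- 0
    }
  }
  if (remaining > dv * 1e-9 && remaining > 1e-15) {
    abort("Internal error: slice chain drained below requested volume.",
          class = "infusim_internal_error")
  }
  acc / dv
}

dq_total <- function(d) {
  if (d$hi < d$lo) 0 else sum(d$vol[seq.int(d$lo, d$hi)])
}

# ---- LIFO stack for mixed fluid pushed back into a branch line ------------
# Backflow reverses plug flow, so the last mixture pushed into the line is
# the first to return when the branch flows forward again.

new_stack <- function(n_drugs, capacity = 256L) {
  s <- new.env(parent = emptyenv())
  s$vol <- numeric(capacity)
  s$frac <- matrix(0, n_drugs, capacity)
  s$top <- 0L
  s
}

st_push <- function(s, dv, frac) {
  if (s$top == length(s$vol)) {
    cap <- length(s$vol)
    s$vol <- c(s$vol, numeric(cap))
    s$frac <- cbind(s$frac, matrix(0, nrow(s$frac), cap))
  }
  s$top <- s$top + 1L
  s$vol[s$top] <- dv
  s$frac[, s$top] <- frac
  invisible(s)
}

# draw up to `dv` from the top; returns list(volume, mixture fractions)
st_draw <- function(s, dv) {
  acc <- numeric(nrow(s$frac))
  drawn <- 0
  while (drawn < dv && s$top > 0L) {
    v <- s$vol[s$top]
    need <- dv - drawn
    if (v <= need) {
      acc <- acc + v * s$frac[, s$top]
      drawn <- drawn + v
      s$top <- s$top - 1L
    } else {
      acc <- acc + need * s$frac[, s$top]
      s$vol[s$top] <- v - need
      drawn <- dv
    }
  }
  list(volume_ml = drawn,
       fractions = if (drawn > 0) acc / drawn else acc)
}

st_total <- function(s) if (s$top == 0L) 0 else sum(s$vol[seq_len(s$top)])
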