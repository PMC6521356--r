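#' Parameter space for sampling
#'
#' An ordered set of sampled quantities with bounds and a per-entry scale.
#' Entries may be rate constants (named by parameter id) or species initial
#' amounts (named `"init:<species id>"`).
#'
#' @param id Character vector of entry ids.
#' @param lower,upper Numeric bounds (lower < upper; log10 scale requires
#'   lower > 0).
#' @param scale `"linear"` or `"log10"`, recycled.
#' @return A `parameter_space` with fields `entries` (data.frame) and `k`.
#' @export
parameter_space <- function(id, lower, upper, scale = "log10") {
  scale <- rep(scale, length.out = length(id))
  stopifnot(length(lower) == length(id), length(upper) == length(id),
            all(scale %in% c("linear", "log10")))
  if (any(lower >= upper)) stop("parameter bounds require lower < upper")
  if (any(scale == "log10" & lower <= 0)) stop("log10 scale requires lower > 0")
  structure(list(entries = data.frame(id = id, lower = lower, upper = upper,
                                      scale = scale, stringsAsFactors = FALSE),
                 k = length(id)),
            class = "parameter_space")
}

#' Default sampling bounds around a network's baseline
#'
#' Rate constants vary log10-uniformly over `[0.1x, 10x]` baseline; initial
#' amounts vary linearly over `[0.5x, 2x]` baseline. Parameters with baseline
#' zero (none in the shipped model) and zero initial amounts are skipped.
#'
#' @param net A `reaction_network`.
#' @param parameters Parameter ids to include (default all).
#' @param initials Species ids whose initial amounts to include (default:
#'   none; pass e.g. `c("HER4","HER2_3")` for a species panel).
#' @param rate_span Multiplicative half-range for rates (default 10).
#' @param init_span `c(low, high)` multipliers for initial amounts.
#' @return A [parameter_space()].
#' @export
default_parameter_space <- function(net, parameters = names(net$parameters),
                                    initials = character(),
                                    rate_span = 10, init_span = c(0.5, 2)) {
  pv <- net$parameters[parameters]
  if (any(pv <= 0)) stop("log10 bounds need positive baseline rates")
  ids <- parameters; lo <- pv / rate_span; hi <- pv * rate_span
  sc <- rep("log10", length(pv))
  if (length(initials) > 0L) {
    iv <- net$species$initial_amount[match(initials, net$species$id)]
    if (anyNA(iv)) stop("unknown species in initials")
    keep <- iv > 0
    ids <- c(ids, paste0("init:", initials[keep]))
    lo <- c(lo, iv[keep] * init_span[1]); hi <- c(hi, iv[keep] * init_span[2])
    sc <- c(sc, rep("linear", sum(keep)))
  }
  parameter_space(ids, lo, hi, sc)
}

#' Latin hypercube sample in the unit hypercube
#'
#' Stratified sample: in every column exactly one point falls in each of the
#' `n` equal strata. Deterministic given `seed`.
#'
#' @param n Number of samples.
#' @param k Dimension.
#' @param seed Integer seed.
#' @return `n x k` matrix in `[0, 1)`.
#' @export
latin_hypercube <- function(n, k, seed) {
  stopifnot(n >= 1, k >= 1)
  u <- withr::with_seed(seed, lhs::randomLHS(n, k))
  # randomLHS draws in (0,1); clamp the open upper end to [0,1)
  pmin(u, 1 - 1e-12)
}

sobol_direction_table <- function() {
  f <- system.file("extdata", "sobol_directions.tsv", package = "her4switch")
  tab <- read.delim(f, stringsAsFactors = FALSE)
  tab$m <- lapply(strsplit(tab$m, " "), as.integer)
  tab
}

SOBOL_BITS <- 31L

# 31-bit direction numbers for one dimension from (s, a, m_1..m_s)
sobol_directions <- function(s, a, m) {
  v <- integer(SOBOL_BITS)
  for (i in seq_len(s)) v[i] <- bitwShiftL(m[i], SOBOL_BITS - i)
  if (SOBOL_BITS > s) {
    abits <- as.integer(intToBits(a))[seq_len(max(s - 1L, 1L))]
    for (i in (s + 1L):SOBOL_BITS) {
      v[i] <- bitwXor(v[i - s], bitwShiftR(v[i - s], s))
      for (kk in seq_len(s - 1L)) {
        # a encodes coefficients a_1..a_{s-1} of the primitive polynomial,
        # most significant bit first
        if (bitwAnd(bitwShiftR(a, s - 1L - kk), 1L) == 1L)
          v[i] <- bitwXor(v[i], v[i - kk])
      }
    }
  }
  v
}

#' Sobol' quasi-random sequence
#'
#' Generates the first `n` points (after dropping `skip` points, counting the
#' initial all-zero point) of the Sobol' low-discrepancy sequence, using a
#' packaged direction-number table (standard published values for the lowest
#' dimensions, verified primitive polynomials above). For `n = 2^m` with
#' `skip` a multiple of `2^m`, every one-dimensional projection places
#' exactly one point in each dyadic interval `[j/2^m, (j+1)/2^m)`.
#'
#' @param n Number of points.
#' @param k Dimension (limited by the packaged table, currently 53).
#' @param skip Number of initial points to drop (burn-in), default 0.
#' @return `n x k` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, k, skip = 0) {
  stopifnot(n >= 0, k >= 1, skip >= 0)
  tab <- sobol_direction_table()
  if (k > nrow(tab) + 1L)
    stop("k = ", k, " exceeds packaged direction-number table (max ",
         nrow(tab) + 1L, ")")
  if (n == 0L) return(matrix(numeric(0), 0L, k))
  V <- matrix(0L, SOBOL_BITS, k)
  V[, 1L] <- bitwShiftL(1L, SOBOL_BITS - seq_len(SOBOL_BITS))
  for (j in seq_len(k - 1L)) {
    row <- tab[j, ]
    V[, j + 1L] <- sobol_directions(row$s, row$a, row$m[[1L]])
  }
  total <- n + skip
  if (total > 2^SOBOL_BITS) stop("sequence too long for 31-bit generator")
  out <- matrix(0, n, k)
  x <- integer(k)
  if (skip == 0L) out[1L, ] <- 0
  for (i in seq_len(total - 1L)) {
    # Gray-code order: flip direction c = lowest zero bit of (i-1)
    val <- i - 1L
    c <- 1L
    while (bitwAnd(val, 1L) == 1L) {
      val <- bitwShiftR(val, 1L)
      c <- c + 1L
    }
    x <- bitwXor(x, V[c, ])
    if (i >= skip) out[i - skip + 1L, ] <- x / 2^SOBOL_BITS
  }
  out
}

#' Map unit-hypercube samples to parameter values
#'
#' Linear entries: `lower + u * (upper - lower)`; log10 entries:
#' `10^(log10(lower) + u * (log10(upper) - log10(lower)))`.
#'
#' @param u Matrix in `[0, 1)`, one column per space entry.
#' @param space A [parameter_space()].
#' @return Matrix of parameter values with entry ids as column names.
#' @export
scale_to_space <- function(u, space) {
  if (!is.matrix(u)) u <- matrix(u, nrow = 1L)
  if (ncol(u) != space$k)
    stop("sample has ", ncol(u), " columns; space has k = ", space$k)
  if (any(u < 0 | u >= 1 + 1e-12)) stop("unit samples must lie in [0, 1)")
  out <- u
  for (j in seq_len(space$k)) {
    e <- space$entries[j, ]
    out[, j] <- if (e$scale == "log10")
      10^(log10(e$lower) + u[, j] * (log10(e$upper) - log10(e$lower)))
    else e$lower + u[, j] * (e$upper - e$lower)
  }
  colnames(out) <- space$entries$id
  out
}

#' Saltelli design for Sobol index estimation
#'
#' Draws one Sobol' sequence of dimension `2k`; columns `1..k` form the base
#' matrix `A`, columns `k+1..2k` the matrix `B`. The hybrid matrices `AB[[i]]`
#' (`A` with column `i` from `B`) and `BA[[i]]` (`B` with column `i` from `A`)
#' supply the product-form estimators of the first-order and total-effect
#' indices. Total implied model evaluations: `N * (2k + 2)`.
#'
#' @param space A [parameter_space()] (defines `k`).
#' @param N Base sample count (>= 2; powers of two give the best uniformity).
#' @param skip Points of the underlying sequence to drop; default the next
#'   power of two `>= N` (standard burn-in).
#' @return A `saltelli_design` with unit-hypercube matrices `A`, `B`, lists
#'   `AB`, `BA`, and fields `N`, `k`, `skip`, `space`.
#' @export
saltelli_design <- function(space, N, skip = NULL) {
  stopifnot(N >= 2)
  k <- space$k
  if (is.null(skip)) skip <- 2^ceiling(log2(N))
  u <- sobol_sequence(N, 2L * k, skip = skip)
  A <- u[, seq_len(k), drop = FALSE]
  B <- u[, k + seq_len(k), drop = FALSE]
  AB <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  BA <- lapply(seq_len(k), function(i) { M <- B; M[, i] <- A[, i]; M })
  structure(list(A = A, B = B, AB = AB, BA = BA, N = N, k = k, skip = skip,
                 space = space), class = "saltelli_design")
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat(sprintf("Saltelli design: N = %d, k = %d, skip = %d (%d model evaluations)\n",
              x$N, x$k, x$skip, x$N * (2L * x$k + 2L)))
  invisible(x)
}

#' Save / load a Saltelli design as CSV with a JSON sidecar
#'
#' The CSV stacks the `A`, `B`, `AB[[i]]`, `BA[[i]]` blocks with `block` and
#' `row` annotation columns; the sidecar records `N`, `k`, `skip` and the
#' parameter space (ids, bounds, scales). On load the column-swap structure
#' of the design is re-asserted.
#'
#' @param design A `saltelli_design`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly (save) or the reconstructed design (load).
#' @export
save_design <- function(design, path) {
  blocks <- c(list(A = design$A, B = design$B),
              setNames(design$AB, paste0("AB", seq_len(design$k))),
              setNames(design$BA, paste0("BA", seq_len(design$k))))
  tab <- do.call(rbind, lapply(names(blocks), function(nm)
    data.frame(block = nm, row = seq_len(nrow(blocks[[nm]])),
               blocks[[nm]], check.names = FALSE)))
  colnames(tab)[-(1:2)] <- design$space$entries$id
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(list(N = design$N, k = design$k, skip = design$skip,
                            space = design$space$entries),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_design
#' @export
load_design <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  space <- parameter_space(meta$space$id, meta$space$lower, meta$space$upper,
                           meta$space$scale)
  tab <- utils::read.csv(path, check.names = FALSE)
  get_block <- function(nm) {
    m <- as.matrix(tab[tab$block == nm, -(1:2), drop = FALSE])
    dimnames(m) <- NULL
    m
  }
  design <- structure(list(
    A = get_block("A"), B = get_block("B"),
    AB = lapply(seq_len(meta$k), function(i) get_block(paste0("AB", i))),
    BA = lapply(seq_len(meta$k), function(i) get_block(paste0("BA", i))),
    N = meta$N, k = meta$k, skip = meta$skip, space = space),
    class = "saltelli_design")
  for (i in seq_len(design$k)) {
    stopifnot(isTRUE(all.equal(design$AB[[i]][, i], design$B[, i])),
              isTRUE(all.equal(design$AB[[i]][, -i], design$A[, -i])),
              isTRUE(all.equal(design$BA[[i]][, i], design$A[, i])),
              isTRUE(all.equal(design$BA[[i]][, -i], design$B[, -i])))
  }
  design
}
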