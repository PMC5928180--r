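#' Synthetic non-negative endmember spectra
#'
#' Draws k peak-shaped spectra of length m: each is a sum of Gaussian peaks
#' at seeded random channel positions with random widths and heights, plus a
#' small smooth baseline — the shape of classical mass spectra. Spectra are
#' resampled (up to 100 attempts) until all pairwise cosines are at or below
#' `max_cosine`, so recovery is well-posed.
#'
#' @param k number of endmembers. @param m number of channels.
#' @param peaks_per_spectrum Gaussian peaks per endmember (>= 1 unless a
#'   baseline is kept).
#' @param seed RNG seed.
#' @param baseline baseline amplitude relative to unit peak height
#'   (default 0.02).
#' @param max_cosine well-posedness bound on pairwise endmember cosine.
#' @return `m x k` non-negative matrix, columns the true endmembers.
#' @export
make_endmembers <- function(k, m, peaks_per_spectrum = 5L, seed = 0L,
                            baseline = 0.02, max_cosine = 0.9) {
  if (k < 1L || m < 1L) stop("k and m must be >= 1", call. = FALSE)
  if (peaks_per_spectrum < 1L && baseline <= 0)
    stop("degenerate endmembers: no peaks and no baseline", call. = FALSE)
  set.seed(seed)
  ch <- seq_len(m)
  draw <- function() {
    U <- matrix(0, m, k)
    for (j in seq_len(k)) {
      s <- rep(0, m)
      if (peaks_per_spectrum >= 1L) for (p in seq_len(peaks_per_spectrum)) {
        pos <- runif(1, 1, m)
        width <- runif(1, max(1, m / 100), max(2, m / 25))
        height <- runif(1, 0.3, 1)
        s <- s + height * exp(-(ch - pos)^2 / (2 * width^2))
      }
      if (baseline > 0)
        s <- s + baseline * (1 + 0.5 * cos(2 * pi * ch / m + runif(1, 0, 2 * pi)))
      U[, j] <- s
    }
    U
  }
  for (attempt in seq_len(100L)) {
    U <- draw()
    if (k < 2L || max_pairwise_cosine(U) <= max_cosine) return(U)
  }
  stop("could not draw endmembers with pairwise cosine <= ", max_cosine,
       " in 100 attempts", call. = FALSE)
}

#' Synthetic abundance fields
#'
#' Builds k spatially smooth, sparse abundance fields over the grid: each
#' component is a mixture of seeded Gaussian blobs with spatial standard
#' deviation `smoothness_scale` px; a `sparsity` fraction of pixels is then
#' made single-endmember dominant (all but the largest component zeroed),
#' reflecting the low probability of many phases coexisting in one pixel;
#' optional per-pixel simplex normalization.
#'
#' @param grid_shape `c(ny, nx)`. @param k components.
#' @param smoothness_scale blob length-scale in px.
#' @param sparsity fraction of pixels forced single-endmember (0..1).
#' @param sum_to_one normalize each pixel's abundances to sum 1.
#' @param seed RNG seed. @param n_blobs blobs per component.
#' @return `k x n` non-negative abundance matrix in raster order.
#' @export
make_abundances <- function(grid_shape, k, smoothness_scale = 8,
                            sparsity = 0.2, sum_to_one = TRUE, seed = 0L,
                            n_blobs = 6L) {
  grid_shape <- as.integer(grid_shape)
  ny <- grid_shape[1]; nx <- grid_shape[2]; n <- ny * nx
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (sparsity < 0 || sparsity > 1) stop("sparsity must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  idx <- raster_index(grid_shape)
  V <- matrix(0, k, n)
  for (j in seq_len(k)) {
    f <- rep(0.02, n)  # small floor keeps every pixel explained
    for (b in seq_len(n_blobs)) {
      cy <- runif(1, 1, ny); cx <- runif(1, 1, nx)
      h <- runif(1, 0.5, 1.5)
      f <- f + h * exp(-((idx[, "y"] - cy)^2 + (idx[, "x"] - cx)^2) /
                         (2 * smoothness_scale^2))
    }
    V[j, ] <- f
  }
  if (sparsity > 0) {
    n_sparse <- round(sparsity * n)
    if (n_sparse > 0) {
      pix <- sample.int(n, n_sparse)
      top <- dominant_endmember(V[, pix, drop = FALSE])
      for (t in seq_along(pix)) {
        keep <- V[top[t], pix[t]]
        V[, pix[t]] <- 0
        V[top[t], pix[t]] <- keep
      }
    }
  }
  if (sum_to_one) V <- simplex_project_cols(V, k, 1e-12)$V
  V
}

#' Synthetic ground truth for a hyperspectral cube
#'
#' @param k,m,grid_shape model size (defaults: 3 endmembers, 200 channels,
#'   32 x 32 grid — the package's frozen verification conditions).
#' @param noise `"gaussian"` (additive, level set by `snr_db`) or `"poisson"`
#'   (counts with mean `poisson_scale * U V`), or `"none"`.
#' @param snr_db signal-to-noise ratio in dB for Gaussian noise (default 30).
#' @param poisson_scale mean counts per unit signal for Poisson noise.
#' @param seed RNG seed controlling endmembers, abundances, and noise.
#' @param ... forwarded to [make_endmembers()] and [make_abundances()]
#'   (`peaks_per_spectrum`, `smoothness_scale`, `sparsity`, `sum_to_one`, ...).
#' @return A `ground_truth` list: `U` (m x k), `V` (k x n), `grid_shape`,
#'   `noise`, `snr_db`/`poisson_scale`, `seed`, and the generator parameters.
#' @export
make_ground_truth <- function(k = 3L, m = 200L, grid_shape = c(32L, 32L),
                              noise = c("gaussian", "poisson", "none"),
                              snr_db = 30, poisson_scale = 100, seed = 0L,
                              ...) {
  noise <- match.arg(noise)
  dots <- list(...)
  em_args <- dots[names(dots) %in% c("peaks_per_spectrum", "baseline", "max_cosine")]
  ab_args <- dots[names(dots) %in% c("smoothness_scale", "sparsity",
                                     "sum_to_one", "n_blobs")]
  U <- do.call(make_endmembers, c(list(k = k, m = m, seed = seed), em_args))
  V <- do.call(make_abundances, c(list(grid_shape = grid_shape, k = k,
                                       seed = seed + 1L), ab_args))
  structure(
    c(list(U = U, V = V, grid_shape = as.integer(grid_shape), noise = noise,
           snr_db = snr_db, poisson_scale = poisson_scale, seed = as.integer(seed)),
      em_args, ab_args),
    class = "ground_truth"
  )
}

#' Realize a ground truth as a noisy hyperspectral cube
#'
#' The linear mixing model: the noiseless cube is exactly the reshaped
#' product `U V`; Gaussian noise is added at the configured SNR (negative
#' values clipped at zero, clip fraction recorded in `meta`), or Poisson
#' counts are drawn with mean `poisson_scale * U V`.
#'
#' @param truth a [make_ground_truth()] object.
#' @return A [hyper_cube()]; `meta$clip_fraction` records Gaussian clipping.
#' @export
make_cube <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  X0 <- truth$U %*% truth$V
  meta <- list(generator = "unmixr_synth", seed = truth$seed,
               noise = truth$noise)
  set.seed(truth$seed + 2L)
  X <- switch(truth$noise,
    none = X0,
    gaussian = {
      sigma <- sqrt(mean(X0^2) / 10^(truth$snr_db / 10))
      Xn <- X0 + matrix(rnorm(length(X0), sd = sigma), nrow(X0), ncol(X0))
      clip <- mean(Xn < 0)
      Xn[Xn < 0] <- 0
      meta$clip_fraction <- clip
      meta$sigma <- sigma
      Xn
    },
    poisson = {
      lam <- truth$poisson_scale * X0
      matrix(rpois(length(lam), lam), nrow(X0), ncol(X0))
    }
  )
  matrix_to_cube(data_matrix(X, grid_shape = truth$grid_shape, meta = meta))
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    sub <- all_permutations(k - 1L)
    out <- c(out, lapply(sub, function(p) c(i, (seq_len(k)[-i])[p])))
  }
  out
}

#' Optimal component matching between two endmember sets
#'
#' Finds the permutation of fitted components maximizing the total cosine
#' similarity to the reference set (exhaustive assignment for k <= 8, greedy
#' beyond).
#'
#' @param U_fit,U_true `m x k` matrices.
#' @return Integer permutation `p`: fitted component `p[i]` matches true
#'   component `i`.
#' @export
match_components <- function(U_fit, U_true) {
  k <- ncol(U_true)
  stopifnot(ncol(U_fit) == k)
  cn <- function(M) {
    s <- sqrt(colSums(M^2)); s[s == 0] <- 1
    col_scale(M, 1 / s)
  }
  S <- crossprod(cn(U_true), cn(U_fit))  # S[i, j] = cos(true i, fit j)
  if (k <= 8L) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) sum(S[cbind(seq_len(k), p)]), 0)
    return(as.integer(perms[[which.max(scores)]]))
  }
  p <- integer(k); used <- logical(k)
  for (i in order(apply(S, 1, max), decreasing = TRUE)) {
    j <- which.max(replace(S[i, ], used, -Inf))
    p[i] <- j; used[j] <- TRUE
  }
  p
}

#' Recovery metrics of a fitted model against generator ground truth
#'
#' Matches fitted to true components by maximum total cosine over
#' permutations, then reports per-component endmember cosines, the abundance
#' RMSE after matching and per-component optimal non-negative rescaling, and
#' the relative reconstruction error against the noiseless truth.
#'
#' @param model a `factor_model` (NMF). @param truth a [make_ground_truth()].
#' @return A list with `permutation`, `cosines` (length k), `mean_cosine`,
#'   `abundance_rmse`, `reconstruction_error`, and the matched factors.
#' @export
recovery_report <- function(model, truth) {
  stopifnot(inherits(model, "factor_model"), inherits(truth, "ground_truth"))
  k <- ncol(truth$U)
  if (ncol(model$U) != k) stop("model and truth k differ", call. = FALSE)
  p <- match_components(model$U, truth$U)
  Uf <- model$U[, p, drop = FALSE]
  Vf <- model$V[p, , drop = FALSE]
  cosv <- vapply(seq_len(k), function(j) {
    a <- Uf[, j]; b <- truth$U[, j]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }, 0)
  # per-component optimal non-negative scale for the abundance comparison
  Vs <- Vf
  for (j in seq_len(k)) {
    denom <- sum(Vf[j, ]^2)
    a <- if (denom > 0) max(0, sum(Vf[j, ] * truth$V[j, ]) / denom) else 0
    Vs[j, ] <- a * Vf[j, ]
  }
  rmse <- sqrt(mean((Vs - truth$V)^2))
  X0 <- truth$U %*% truth$V
  rec <- sqrt(sum((X0 - Uf %*% Vf)^2)) / sqrt(sum(X0^2))
  list(permutation = p, cosines = cosv, mean_cosine = mean(cosv),
       abundance_rmse = rmse, reconstruction_error = rec,
       U_matched = Uf, V_matched = Vs)
}
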