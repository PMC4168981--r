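#' Artificially-centered hit-and-run sampling of the sub-optimal flux space
#'
#' Samples the polytope \{S v = 0, lb <= v <= ub, c'v >= fraction * opt\}
#' where opt is the FBA optimum of the model objective. Warmup points are
#' corner solutions from randomized objectives; the sampler then runs
#' \code{n_points} parallel chains (initialized as random convex combinations
#' of warmup points), and on every sweep moves each chain along the direction
#' from a randomly chosen chain to the running center of mass, by a uniform
#' step within the feasible chord. The half-way snapshot of the chain set is
#' retained for the mixed-fraction convergence diagnostic. All chain moves
#' stay inside the affine space S v = 0 because directions are differences of
#' feasible points.
#'
#' @param model a feasible \code{metabolic_model}.
#' @param n_points number of chains = number of returned sample points.
#' @param n_steps sweeps per chain (every chain moves once per sweep).
#' @param optimality_fraction lower bound on the objective as a fraction of
#'   the FBA optimum (0 disables the constraint; 0.9 is the conventional
#'   sub-optimal growth bound used throughout this pipeline).
#' @param seed integer seed; identical seeds give identical sample matrices.
#' @return object of class \code{flux_sample_set}: \code{points}
#'   (n_points x n_reactions), \code{reactions}, \code{half} (half-way
#'   snapshot), \code{config}, \code{normalized = FALSE}.
#' @export
achr_sample <- function(model, n_points = 5000, n_steps = 100,
                        optimality_fraction = 0.9, seed = 1L) {
  stopifnot(optimality_fraction >= 0, optimality_fraction <= 1)
  set.seed(seed)
  rxns <- reaction_ids(model)
  n <- length(rxns)
  bounds <- model_bounds(model)
  S <- stoich_matrix(model)
  obj <- objective_vector(model)
  extraA <- NULL; extrab <- NULL
  if (optimality_fraction > 0 && any(obj != 0)) {
    opt <- fba(model)$objective_value
    extraA <- matrix(-obj, nrow = 1)
    extrab <- -optimality_fraction * opt
  }
  # warmup: corners of randomized objectives (each coordinate direction,
  # both senses, with small random fill to spread over optimal faces)
  warm <- matrix(NA_real_, nrow = 2L * n, ncol = n)
  k <- 0L
  for (i in seq_len(n)) {
    for (sgn in c(1, -1)) {
      w <- stats::rnorm(n, 0, 0.01)
      w[i] <- sgn
      sol <- lp_solve(stats::setNames(w, rxns), S, bounds$lb, bounds$ub,
                      maximize = TRUE, extraA = extraA, extrab = extrab)
      if (!sol$feasible) {
        stop("sampling polytope infeasible at optimality fraction ",
             optimality_fraction)
      }
      k <- k + 1L
      warm[k, ] <- sol$v
    }
  }
  # inequality system G v <= h describing the polytope faces (bounds and the
  # optimality constraint); used for the chord computation
  G <- rbind(diag(n), -diag(n), extraA)
  h <- c(bounds$ub, -bounds$lb, extrab)
  # chains: random convex combinations of warmup points
  wts <- matrix(stats::rexp(n_points * nrow(warm)), nrow = n_points)
  wts <- wts / rowSums(wts)
  pts <- wts %*% warm
  center <- colMeans(pts)
  half <- NULL
  half_at <- max(1L, floor(n_steps / 2))
  eps <- 1e-11
  for (step in seq_len(n_steps)) {
    dirs <- pts[sample.int(n_points), , drop = FALSE] -
      matrix(center, n_points, n, byrow = TRUE)
    P <- pts %*% t(G)
    D <- dirs %*% t(G)
    R <- (matrix(h, n_points, length(h), byrow = TRUE) - P) / D
    Rpos <- ifelse(D > eps, R, Inf)
    Rneg <- ifelse(D < -eps, R, -Inf)
    tmax <- as.numeric(do.call(pmin, lapply(seq_len(ncol(Rpos)), function(j) Rpos[, j])))
    tmin <- as.numeric(do.call(pmax, lapply(seq_len(ncol(Rneg)), function(j) Rneg[, j])))
    tmax[!is.finite(tmax)] <- 0
    tmin[!is.finite(tmin)] <- 0
    width <- pmax(tmax - tmin, 0)
    t <- tmin + stats::runif(n_points) * width
    t[width <= 0] <- 0
    pts <- pts + dirs * t
    # clamp microscopic overshoot onto the box
    pts <- pmin(pmax(pts, matrix(bounds$lb, n_points, n, byrow = TRUE)),
                matrix(bounds$ub, n_points, n, byrow = TRUE))
    center <- colMeans(pts)
    if (step == half_at) half <- pts
  }
  colnames(pts) <- rxns
  colnames(half) <- rxns
  structure(list(points = pts, reactions = rxns, half = half,
                 config = list(n_points = n_points, n_steps = n_steps,
                               optimality_fraction = optimality_fraction,
                               seed = seed,
                               variant = paste0(
                                 "parallel-chain ACHR: per sweep each chain ",
                                 "moves along (random chain - running center) ",
                                 "by a uniform step within the feasible chord; ",
                                 "warmup = 2n randomized-objective corners")),
                 normalized = FALSE),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set>", nrow(x$points), "points x", ncol(x$points),
      "reactions;", if (x$normalized) "normalized" else "raw", "\n")
  invisible(x)
}

#' Mixed-fraction convergence diagnostic
#'
#' For each reaction the median of the final sample defines two sides; the
#' statistic is the fraction of (chain, reaction) pairs whose side differs
#' between the half-way snapshot and the final snapshot. Well-mixed chains
#' forget their half-way position, giving approximately 0.5; frozen chains
#' give 0. Reactions with constant final samples are excluded.
#'
#' @param samples a \code{flux_sample_set} with a half-way snapshot.
#' @return the mixed fraction, a value in [0, 1].
#' @export
mixed_fraction <- function(samples) {
  if (is.null(samples$half)) stop("sample set carries no half-way snapshot")
  fin <- samples$points
  hal <- samples$half
  if (nrow(fin) < 4L) stop("too few points for the diagnostic")
  keep <- apply(fin, 2, function(x) diff(range(x)) > 1e-9)
  if (!any(keep)) stop("all reaction columns constant")
  fin <- fin[, keep, drop = FALSE]
  hal <- hal[, keep, drop = FALSE]
  med <- apply(fin, 2, stats::median)
  medm <- matrix(med, nrow(fin), ncol(fin), byrow = TRUE)
  mean((fin > medm) != (hal > medm))
}

#' Drop zero-flux and loop reactions before differential analysis
#'
#' A reaction is zero in a sample set when its |flux| stays below \code{tol}
#' in at least 99% of points; reactions zero in both conditions are dropped.
#' Loop reactions are those able to carry flux when every exchange reaction
#' is closed (flux variability on the closed network has nonzero range):
#' thermodynamically infeasible internal cycles that would contaminate the
#' comparison.
#'
#' @param samplesA,samplesB two \code{flux_sample_set}s (shared reaction
#'   names where they coincide).
#' @param model the model whose topology defines exchanges and loops.
#' @param tol zero-flux tolerance.
#' @return character vector of retained reaction ids.
#' @export
filter_zero_and_loop_reactions <- function(samplesA, samplesB, model,
                                           tol = 1e-6) {
  shared <- intersect(colnames(samplesA$points), colnames(samplesB$points))
  zeroish <- function(s) {
    vapply(shared, function(r) {
      if (!r %in% colnames(s$points)) return(TRUE)
      mean(abs(s$points[, r]) < tol) >= 0.99
    }, logical(1))
  }
  zero_both <- zeroish(samplesA) & zeroish(samplesB)
  loops <- loop_reactions(model, tol = tol)
  setdiff(shared[!zero_both], loops)
}

#' Reactions able to carry flux with all exchanges closed
#' @param model a \code{metabolic_model}.
#' @param tol flux tolerance.
#' @return character vector of loop-capable reaction ids.
#' @export
loop_reactions <- function(model, tol = 1e-6) {
  ex <- reaction_ids(model)[vapply(model$reactions, function(r)
    isTRUE(r$is_exchange), logical(1))]
  b <- model_bounds(model)
  # relax forced demands (e.g. maintenance) so the zero state is feasible;
  # only cycle-carrying capability matters here
  closed <- set_bounds(model, reaction_ids(model),
                       lb = pmin(b$lb, 0), ub = pmax(b$ub, 0))
  closed <- set_bounds(closed, ex, lb = 0, ub = 0)
  closed$objective <- numeric(0)
  rng <- fva_raw(closed)
  rng$reaction[rng$max > tol | rng$min < -tol]
}

# FVA without an objective constraint (objective may be empty)
fva_raw <- function(model) {
  S <- stoich_matrix(model)
  bounds <- model_bounds(model)
  ids <- reaction_ids(model)
  out <- data.frame(reaction = ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    e <- stats::setNames(numeric(length(ids)), ids)
    e[ids[i]] <- 1
    lo <- lp_solve(e, S, bounds$lb, bounds$ub, maximize = FALSE)
    hi <- lp_solve(e, S, bounds$lb, bounds$ub, maximize = TRUE)
    if (!lo$feasible || !hi$feasible) stop("FVA subproblem infeasible")
    out$min[i] <- lo$objective
    out$max[i] <- hi$objective
  }
  out
}

#' Normalize sampled fluxes to relative magnitudes
#'
#' Divides each sample point by its total flux magnitude, so that per point
#' the absolute normalized fluxes sum to one. Signs are preserved. Apply
#' after \code{filter_zero_and_loop_reactions} so removed loops do not
#' distort the denominator.
#'
#' @param samples a raw \code{flux_sample_set}.
#' @param rxns optional reaction subset to retain (typically the filter's
#'   output) before normalizing.
#' @return a normalized \code{flux_sample_set}.
#' @export
normalize_fluxes <- function(samples, rxns = NULL) {
  if (isTRUE(samples$normalized)) stop("sample set already normalized")
  pts <- samples$points
  if (!is.null(rxns)) {
    missing <- setdiff(rxns, colnames(pts))
    if (length(missing)) stop("unknown reactions: ",
                              paste(missing, collapse = ", "))
    pts <- pts[, rxns, drop = FALSE]
  }
  tot <- rowSums(abs(pts))
  if (any(tot <= 0)) stop("sample point with zero total flux magnitude")
  samples$points <- pts / tot
  samples$reactions <- colnames(pts)
  samples$half <- NULL
  samples$normalized <- TRUE
  samples
}
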