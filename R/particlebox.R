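#' @include proteospread-package.R
NULL

# Reflect positions into [0, side] (reflecting walls).
.reflect <- function(x, side) {
  x <- x %% (2 * side)
  ifelse(x > side, 2 * side - x, x)
}

#' Particle-level misfolding simulation in a cube
#'
#' The ground-truth micro-experiment behind the product-form misfolding
#' law: normal and pathogenic molecules perform Brownian motion (per-axis
#' Gaussian steps, reflecting walls) inside a cube, and a normal molecule
#' converts whenever it comes within `contactRadius` of a pathogenic one.
#' Conversion is resolved synchronously after each step; newly converted
#' molecules template from the next step onward. The defaults keep the
#' expected per-molecule conversion hazard below about 0.25 over the run --
#' the dilute regime in which templating is a binary-encounter process and
#' the mass-action product `RM * Cn * Cp` is the appropriate aggregate
#' model -- while using enough molecules per cell that the Monte-Carlo
#' noise of the converted counts stays small relative to the signal.
#'
#' @param nNormal,nPathogenic initial molecule counts.
#' @param steps number of Brownian steps.
#' @param side cube side (arbitrary length units).
#' @param contactRadius conversion proximity criterion.
#' @param stepSd per-axis Gaussian displacement standard deviation.
#' @param capacity molecule count corresponding to concentration 1 (maps
#'   counts to concentration fractions).
#' @param seed RNG seed (caller's RNG state preserved).
#' @return list with `converted` (count), `convertedConcentration`
#'   (count / capacity), `fractionConverted`, `conversionSteps` (cumulative
#'   conversions per step) and the inputs.
#' @export
runBox <- function(nNormal, nPathogenic, steps = 200L, side = 1,
                   contactRadius = 0.02, stepSd = 0.02, capacity = 500,
                   seed = 1L) {
  stopifnot(nNormal >= 0, nPathogenic >= 0, steps >= 0, side > 0,
            contactRadius > 0, stepSd > 0, capacity > 0)
  run <- function() {
    nTot <- nNormal + nPathogenic
    if (nTot == 0 || nNormal == 0 || nPathogenic == 0) {
      return(list(converted = 0L, steps = integer(max(steps, 0L))))
    }
    pos <- matrix(runif(3 * nTot, 0, side), ncol = 3)
    pathogenic <- c(rep(FALSE, nNormal), rep(TRUE, nPathogenic))
    cum <- integer(steps)
    for (st in seq_len(steps)) {
      pos <- .reflect(pos + matrix(rnorm(3 * nTot, 0, stepSd), ncol = 3), side)
      ni <- which(!pathogenic)
      pi_ <- which(pathogenic)
      if (length(ni) && length(pi_)) {
        # squared cross-distances normal x pathogenic
        d2 <- outer(rowSums(pos[ni, , drop = FALSE]^2),
                    rowSums(pos[pi_, , drop = FALSE]^2), "+") -
          2 * pos[ni, , drop = FALSE] %*% Matrix::t(pos[pi_, , drop = FALSE])
        hit <- ni[apply(d2 <= contactRadius^2, 1, any)]
        if (length(hit)) pathogenic[hit] <- TRUE
      }
      cum[st] <- sum(pathogenic) - nPathogenic
    }
    list(converted = sum(pathogenic) - nPathogenic, steps = cum)
  }
  res <- if (is.null(seed)) run() else withSeed(seed, run())
  list(converted = res$converted,
       convertedConcentration = res$converted / capacity,
       fractionConverted = if (nNormal > 0) res$converted / nNormal else 0,
       conversionSteps = res$steps,
       nNormal = nNormal, nPathogenic = nPathogenic,
       steps = steps, side = side, contactRadius = contactRadius,
       stepSd = stepSd, capacity = capacity, seed = seed)
}

#' Converted-concentration surface over a grid of initial concentrations
#'
#' Runs [runBox()] over all combinations of initial normal and pathogenic
#' counts, averaging the converted concentration over seeds.
#'
#' @param normalCounts,pathogenicCounts integer vectors of initial counts.
#' @param seeds integer vector of seeds to average over.
#' @param ... forwarded to [runBox()].
#' @return data.frame `Cn0`, `Cp0` (concentration fractions), `nNormal`,
#'   `nPathogenic`, `converted` (mean converted concentration).
#' @export
misfoldGrid <- function(normalCounts = seq(5, 40, by = 5),
                        pathogenicCounts = seq(5, 40, by = 5),
                        seeds = 1:10, ...) {
  dots <- list(...)
  capacity <- if (is.null(dots$capacity)) 500 else dots$capacity
  grid <- expand.grid(nNormal = normalCounts, nPathogenic = pathogenicCounts)
  conv <- mapply(function(nn, np) {
    mean(vapply(seeds, function(s)
      do.call(runBox, c(list(nNormal = nn, nPathogenic = np, seed = s),
                        dots))$convertedConcentration,
      numeric(1)))
  }, grid$nNormal, grid$nPathogenic)
  data.frame(Cn0 = grid$nNormal / capacity, Cp0 = grid$nPathogenic / capacity,
             nNormal = grid$nNormal, nPathogenic = grid$nPathogenic,
             converted = conv)
}

#' Fit the product-form misfolding model to a converted-concentration grid
#'
#' Least-squares fit of `RM * Cn0 * Cp0` (scale through the origin) to the
#' simulated converted concentrations; the goodness of fit quantifies how
#' well the product of the two concentrations models the particle-level
#' ground truth.
#'
#' @param grid data.frame with `Cn0`, `Cp0`, `converted` (as from
#'   [misfoldGrid()]).
#' @return list with `RM` (fitted scale), `r.squared`, `fitted`.
#' @export
fitProductModel <- function(grid) {
  stopifnot(all(c("Cn0", "Cp0", "converted") %in% names(grid)))
  if (nrow(grid) < 16 || length(unique(grid$Cn0)) < 4 ||
      length(unique(grid$Cp0)) < 4)
    stop("need at least a 4x4 grid of initial concentrations")
  x <- grid$Cn0 * grid$Cp0
  y <- grid$converted
  if (sum(x^2) == 0) stop("degenerate grid: all products zero")
  rm_ <- sum(x * y) / sum(x^2)
  fitted <- rm_ * x
  ssRes <- sum((y - fitted)^2)
  ssTot <- sum((y - mean(y))^2)
  list(RM = rm_, r.squared = if (ssTot > 0) 1 - ssRes / ssTot else NA_real_,
       fitted = fitted)
}
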