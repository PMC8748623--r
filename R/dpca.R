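## Demixed principal component analysis: decomposing trial-averaged
## population activity into stimulus, decision, condition-independent and
## interaction components.

dpcaMargNames <- function() c("time", "stimulus", "decision", "interaction")

#' Marginalize a condition-averaged activity tensor
#'
#' Centres the tensor per unit (over all conditions and times) and splits it
#' additively into the condition-independent (time), stimulus x time,
#' decision x time, and stimulus x decision x time marginal averages. The
#' four marginalizations sum exactly to the centred tensor and are mutually
#' orthogonal in the variance sense for balanced designs.
#'
#' @param tensor 4-d array units x stimuli x decisions x time of
#'   trial-averaged rates (balanced condition means).
#' @return list with \code{centered} (the centred tensor),
#'   \code{marginalizations} (named list of 4-d arrays) and
#'   \code{unitMeans}.
#' @export
dpcaMarginalize <- function(tensor) {
  d <- dim(tensor)
  failIf(length(d) != 4, "tensor must be units x stimuli x decisions x time")
  failIf(anyNA(tensor), "missing condition cell in the activity tensor")
  nU <- d[1]
  unitMeans <- apply(tensor, 1, mean)
  X <- sweep(tensor, 1, unitMeans)
  expand <- function(a, dims) {
    ## broadcast a reduced array (averaged over `dims`) back to full size
    for (dd in sort(dims)) {
      a <- array(rep(a, times = d[dd]),
                 dim = c(dim(a), d[dd]))
      perm <- seq_along(dim(a))
      ## move the new trailing dim back into position dd
      perm <- append(perm[-length(perm)], length(perm), after = dd - 1)
      a <- aperm(a, perm)
    }
    a
  }
  mTime <- expand(apply(X, c(1, 4), mean), c(2, 3))
  mStim <- expand(apply(X, c(1, 2, 4), mean), 3) - mTime
  mDec <- expand(apply(X, c(1, 3, 4), mean), 2) - mTime
  mInt <- X - mTime - mStim - mDec
  list(centered = X,
       marginalizations = list(time = mTime, stimulus = mStim,
                               decision = mDec, interaction = mInt),
       unitMeans = unitMeans)
}

flattenTensor <- function(a) {
  d <- dim(a)
  matrix(a, nrow = d[1])
}

#' Fit demixed PCA
#'
#' For each marginalization, finds the rank-constrained, ridge-penalized
#' reduced-rank regression of the marginalized average onto the full centred
#' data: decoder/encoder pairs minimizing
#' \eqn{\|X_\phi - F D X\|^2 + \lambda \|F D\|^2}. With a single nonzero
#' marginalization and \eqn{\lambda = 0} the components coincide with the
#' PCA of that marginalization. Explained variance is reported against the
#' total centred variance.
#'
#' @param marg output of \code{\link{dpcaMarginalize}}.
#' @param nComponents components per marginalization (default 5).
#' @param lambda ridge penalty; default \code{1e-6} times the total centred
#'   variance.
#' @return a \linkS4class{DpcaFit}.
#' @export
dpcaFit <- function(marg, nComponents = 5, lambda = NULL) {
  X <- flattenTensor(marg$centered)
  nU <- nrow(X)
  totVar <- sum(X^2)
  if (is.null(lambda)) lambda <- 1e-6 * totVar
  failIf(lambda < 0, "lambda must be >= 0")
  G <- X %*% t(X)
  Ginv <- tryCatch(solve(G + diag(lambda + 1e-12 * totVar / nU, nU)),
                   error = function(e)
                     stop("centred data Gram matrix is singular; increase lambda",
                          call. = FALSE))
  encoders <- list(); decoders <- list()
  vt <- list()
  for (mn in dpcaMargNames()) {
    Xf <- flattenTensor(marg$marginalizations[[mn]])
    q <- min(nComponents, nU, ncol(X))
    W <- Xf %*% t(X) %*% Ginv
    sv <- svd(W %*% X, nu = q, nv = 0)
    rank_ <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-12)
    if (rank_ < q) q <- max(rank_, 1L)
    Fq <- sv$u[, seq_len(q), drop = FALSE]
    Dq <- t(Fq) %*% W
    encoders[[mn]] <- Fq
    decoders[[mn]] <- Dq
    ## cumulative explained variance of the marginalization, against total
    prev <- 0
    for (ci in seq_len(q)) {
      Rc <- Fq[, seq_len(ci), drop = FALSE] %*%
        Dq[seq_len(ci), , drop = FALSE] %*% X
      cum <- (sum(Xf^2) - sum((Xf - Rc)^2)) / totVar
      vt[[length(vt) + 1L]] <- data.frame(
        marginalization = mn, component = ci,
        evar_share = cum - prev, cum_evar_share = cum,
        stringsAsFactors = FALSE)
      prev <- cum
    }
  }
  new("DpcaFit", encoders = encoders, decoders = decoders,
      varianceTable = do.call(rbind, vt), lambda = lambda,
      unitMeans = marg$unitMeans, dims = dim(marg$centered))
}

#' Project activity onto dPCA components
#'
#' Applies a fit's decoders to (centred) activity, returning per-component,
#' per-condition time courses.
#'
#' @param fit a \linkS4class{DpcaFit}.
#' @param tensor 4-d activity array matching the fit's unit dimension (raw;
#'   the fit's unit means are removed).
#' @return named list per marginalization of arrays components x stimuli x
#'   decisions x time.
#' @export
dpcaProject <- function(fit, tensor) {
  d <- dim(tensor)
  failIf(d[1] != fit@dims[1], "unit dimension mismatch: %d vs %d", d[1],
         fit@dims[1])
  X <- flattenTensor(sweep(tensor, 1, fit@unitMeans))
  out <- list()
  for (mn in names(fit@decoders)) {
    Y <- fit@decoders[[mn]] %*% X
    out[[mn]] <- array(Y, dim = c(nrow(Y), d[2], d[3], d[4]))
  }
  out
}

#' Condition-averaged tensor from a dataset
#'
#' Builds the units x stimulus(8) x decision(2) x time tensor of
#' trial-averaged binned rates used by dPCA: peripheral cue locations only,
#' decision = match/nonmatch label (applied to the passive task as well,
#' where no behavioural decision occurs).
#'
#' @param ds an \linkS4class{ExperimentDataset}.
#' @param task task block.
#' @param phases phases to pool (default all).
#' @param binS bin width, s (default 0.1).
#' @param correctOnly use correct trials only.
#' @return 4-d array with dimnames; cells lacking trials are NA.
#' @export
dpcaTensor <- function(ds, task, phases = NULL, binS = 0.1,
                       correctOnly = TRUE) {
  periph <- peripheralLocations()
  winEnd <- Inf
  pools <- list()
  for (s in sessions(ds)) {
    if (!is.null(phases) && !(s@phase %in% phases)) next
    tr <- trials(s)
    rows <- which(tr$task == task & (tr$correct | !correctOnly) &
                    tr$cue_location != 4L)
    if (!length(rows)) next
    winEnd <- min(winEnd, min(tr$t_end[rows] - tr$t_cue_on[rows]))
    for (u in spikeUnits(s)) {
      pools[[length(pools) + 1L]] <- list(
        spikes = u$spikes[rows], cue = tr$cue_location[rows],
        match = tr$is_match[rows], cueOn = tr$t_cue_on[rows])
    }
  }
  failIf(length(pools) == 0, "no eligible units")
  fix <- taskTiming(ds)@fixationS
  starts <- seq(-fix, winEnd - binS + 1e-9, by = binS)
  tensor <- array(NA_real_, dim = c(length(pools), 8, 2, length(starts)))
  for (ui in seq_along(pools)) {
    p <- pools[[ui]]
    for (si in seq_along(periph)) {
      for (di in 1:2) {
        idx <- which(p$cue == periph[si] & p$match == (di == 2))
        if (!length(idx)) next
        counts <- vapply(starts, function(st)
          mean(vapply(idx, function(k)
            countInWindow(p$spikes[[k]] - p$cueOn[k], st, st + binS),
            numeric(1))), numeric(1))
        tensor[ui, si, di, ] <- counts / binS
      }
    }
  }
  dimnames(tensor) <- list(NULL, as.character(periph),
                           c("nonmatch", "match"), NULL)
  tensor
}
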