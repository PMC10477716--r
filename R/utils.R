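#' Derive a stage-specific seed from a global seed
#'
#' One global seed deterministically spawns per-stage seeds by hashing the
#' stage name (FNV-1a over the UTF-8 bytes) and folding it into the global
#' seed modulo 2^31 - 1, so that stages draw from unrelated streams while
#' the whole pipeline stays reproducible from a single integer.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  out <- (as.numeric(seed) %% 2147483647 + h) %% 2147483646 + 1
  as.integer(out)
}

# trapezoidal integral on an irregular grid; NA cells dropped pairwise
.trapz <- function(x, y) {
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  pracma::trapz(x, y)
}

# unfold a sample x em x ex array into sample x (em*ex), column-major em-first
.unfoldCube <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1], ncol = d[2] * d[3])
}

.foldCube <- function(mat, nEm, nEx) {
  array(mat, dim = c(nrow(mat), nEm, nEx))
}

# best bijective matching between two component sets maximizing the summed
# min(TCC_ex, TCC_em); exhaustive over permutations (R is small)
.matchComponentsBijective <- function(exA, emA, exB, emB) {
  R <- ncol(exA)
  stopifnot(ncol(exB) == R)
  tccEx <- matrix(0, R, R)
  tccEm <- matrix(0, R, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      tccEx[i, j] <- tuckerCongruence(exA[, i], exB[, j])
      tccEm[i, j] <- tuckerCongruence(emA[, i], emB[, j])
    }
  }
  perms <- .permutations(R)
  score <- apply(perms, 1, function(p) {
    sum(pmin(tccEx[cbind(seq_len(R), p)], tccEm[cbind(seq_len(R), p)]))
  })
  best <- perms[which.max(score), ]
  list(
    perm = best,
    tccEx = tccEx[cbind(seq_len(R), best)],
    tccEm = tccEm[cbind(seq_len(R), best)]
  )
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

# sample x emission matrix at a (possibly off-lattice) excitation, by
# linear interpolation between the bracketing grid columns
.exSlice <- function(cube, ex) {
  grid <- exGrid(cube)
  vals <- intensities(cube)
  n <- dim(vals)[1]
  col <- function(i) matrix(vals[, , i], nrow = n)
  if (ex %in% grid) return(col(which(grid == ex)))
  .stopIfNot(ex > min(grid) && ex < max(grid),
             sprintf("excitation %g nm outside grid", ex))
  lo <- max(which(grid < ex))
  hi <- min(which(grid > ex))
  w <- (ex - grid[lo]) / (grid[hi] - grid[lo])
  (1 - w) * col(lo) + w * col(hi)
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
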