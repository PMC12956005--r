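#' @include AllClasses.R hbonds.R
NULL

# Run a function under a local, restored RNG state so stochastic outputs
# are bit-reproducible without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.topologyKey <- function(structure) {
  at <- atoms(structure)
  paste(at$chain, at$resseq, at$icode, at$name, sep = "|")
}

#' Per-frame interchain water-bridge counts over a trajectory
#'
#' Applies [findWaterBridges()] to every frame of a multi-model PDB
#' trajectory (or an explicit list of structures) and returns the bridge
#' count series. All frames must share one topology (same atom identity
#' set); frame times are the model index times the save interval, with the
#' first saved frame at one save interval (production-only trajectory).
#'
#' @param frames list of [PDBStructure-class], or a path / PDB text parsed
#'   with [parsePDB()].
#' @param chainA,chainB protomer chain ids.
#' @param config an [AnalysisConfig-class]; `bridgeMetric` selects the
#'   counting metric.
#' @param saveInterval frame spacing in ns (default 2, the cadence of the
#'   recorded MD protocol).
#' @param sourceLabel condition label stored with the series.
#' @param protocol optional [MDProtocol-class]; when given, a mismatch
#'   between the frame count and `expectedFrames(protocol)` is reported as
#'   a warning (the series is still returned).
#' @return a [BridgeTimeSeries-class].
#' @export
bridgeTimeSeries <- function(frames, chainA = "A", chainB = "B",
                             config = analysisConfig(), saveInterval = 2,
                             sourceLabel = "", protocol = NULL) {
  if (is.character(frames)) frames <- parsePDB(frames)
  if (is(frames, "PDBStructure")) frames <- list(frames)
  if (!length(frames)) stop("no frames supplied", call. = FALSE)
  topo <- .topologyKey(frames[[1L]])
  counts <- integer(length(frames))
  for (i in seq_along(frames)) {
    if (i > 1L) {
      ti <- .topologyKey(frames[[i]])
      if (!identical(sort(ti), sort(topo)))
        stop(sprintf("topology drift at frame %d: atom identity set differs from frame 1", i),
             call. = FALSE)
    }
    br <- findWaterBridges(frames[[i]], chainA, chainB, config)
    counts[i] <- countBridges(br, config@bridgeMetric)
  }
  if (!is.null(protocol)) {
    nf <- expectedFrames(protocol)
    if (nf != length(frames))
      warning(sprintf("frame count %d does not match protocol expectation %d",
                      length(frames), nf), call. = FALSE)
  }
  new("BridgeTimeSeries",
      frameTimes = seq_along(frames) * saveInterval,
      counts = counts, metric = config@bridgeMetric,
      sourceLabel = sourceLabel)
}

#' Summarise a bridge-count series
#'
#' Arithmetic mean and standard deviation, non-overlapping block means,
#' and a percentile block-bootstrap 95% confidence interval of the mean.
#' Blocks (default 5 frames, 10 ns at a 2 ns cadence) absorb the frame
#' autocorrelation of an MD trajectory.
#'
#' @param series a [BridgeTimeSeries-class].
#' @param blockLen block length in frames.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @return list with `mean`, `sd`, `blockMeans`, `ci95`, `blockLen`,
#'   `seed`.
#' @export
summarizeSeries <- function(series, blockLen = 5, nBoot = 1000, seed = 1) {
  x <- as.numeric(series@counts)
  n <- length(x)
  if (!n) stop("empty series", call. = FALSE)
  if (blockLen > n)
    stop(sprintf("blockLen (%d) exceeds the number of frames (%d)",
                 as.integer(blockLen), n), call. = FALSE)
  nb <- n %/% blockLen
  bm <- vapply(seq_len(nb), function(b)
    mean(x[((b - 1L) * blockLen + 1L):(b * blockLen)]), numeric(1))
  ci <- if (nb >= 2L) {
    boot <- .withSeed(seed, {
      vapply(seq_len(nBoot), function(r)
        mean(bm[sample.int(nb, nb, replace = TRUE)]), numeric(1))
    })
    unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  } else {
    c(mean(x), mean(x))
  }
  # the interval always contains the point estimate
  ci <- c(min(ci[1L], mean(x)), max(ci[2L], mean(x)))
  list(mean = mean(x), sd = stats::sd(x), blockMeans = bm, ci95 = ci,
       blockLen = as.integer(blockLen), seed = as.integer(seed))
}

#' Compare two bridge-count series
#'
#' Difference of means with a percentile block-bootstrap confidence
#' interval: blocks of each series are resampled independently and the
#' difference of resampled means recorded. Deterministic given the seed.
#'
#' @param a,b [BridgeTimeSeries-class] objects computed under the same
#'   metric.
#' @param seed RNG seed.
#' @param blockLen block length in frames.
#' @param nBoot bootstrap replicates.
#' @return list with `labelA`, `labelB`, `meanDiff` (mean(a) - mean(b)),
#'   `ci95`, `seed`.
#' @export
compareStates <- function(a, b, seed = 1, blockLen = 5, nBoot = 1000) {
  if (!identical(a@metric, b@metric))
    stop("series metrics differ: ", a@metric, " vs ", b@metric,
         call. = FALSE)
  xa <- as.numeric(a@counts)
  xb <- as.numeric(b@counts)
  if (!length(xa) || !length(xb)) stop("empty series", call. = FALSE)
  bl <- min(blockLen, length(xa), length(xb))
  bmA <- summarizeSeries(a, bl, nBoot = 1L, seed = seed)$blockMeans
  bmB <- summarizeSeries(b, bl, nBoot = 1L, seed = seed)$blockMeans
  nA <- length(bmA); nB <- length(bmB)
  boot <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(r)
      mean(bmA[sample.int(nA, nA, replace = TRUE)]) -
        mean(bmB[sample.int(nB, nB, replace = TRUE)]), numeric(1))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  list(labelA = a@sourceLabel, labelB = b@sourceLabel,
       meanDiff = mean(xa) - mean(xb), ci95 = ci, seed = as.integer(seed))
}

#' Write a bridge series as TSV
#'
#' Columns `time_ns`, `count`, `metric`, `label`.
#' @param series a [BridgeTimeSeries-class].
#' @param path output file.
#' @export
writeSeriesTSV <- function(series, path) {
  df <- data.frame(time_ns = series@frameTimes, count = series@counts,
                   metric = series@metric, label = series@sourceLabel)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
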