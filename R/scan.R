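## Orchestration of the full study: volume grid, steady-state
## initialization, replicate SSA runs, per-species sampling-frequency
## selection, spectral and time-domain statistics, deterministic parallel
## reduction, and CSV/JSON export.

#' Construct a scan configuration
#'
#' @param networkPath reaction-table file (defaults to the packaged
#'   signalling network).
#' @param preset \code{"desk"} (default: 4 volumes, 2 replicates, 10 s
#'   windows - minutes on one CPU) or \code{"full"} (the published study
#'   design: 300 equidistant volumes between 5e-16 and 1e-13 l, 100 s
#'   time-domain windows, 10 s spectral windows; needs a large machine).
#' @param ... slot overrides, see \linkS4class{ScanConfig}.
#' @return A \linkS4class{ScanConfig}.
#' @export
scanConfig <- function(networkPath = packagedNetworkPath(),
                       preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "full")
    list(nVolumes = 300L, tStats = 100, tPSD = 10, replicates = 10L)
  else
    list(nVolumes = 4L, tStats = 10, tPSD = 10, replicates = 2L)
  args <- utils::modifyList(c(list(networkPath = networkPath), base),
                            list(...))
  do.call(new, c(list("ScanConfig"), args))
}

#' Read / write a scan configuration as JSON
#'
#' Field names mirror the \linkS4class{ScanConfig} slots.
#'
#' @param path JSON file path.
#' @param cfg a \linkS4class{ScanConfig}.
#' @return A \linkS4class{ScanConfig} (read) or \code{path} (write).
#' @export
readScanConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (s in c("nVolumes", "replicates", "smoothingM", "masterSeed",
              "nWorkers"))
    if (!is.null(x[[s]])) x[[s]] <- as.integer(x[[s]])
  do.call(new, c(list("ScanConfig"), x))
}

#' @rdname readScanConfig
#' @export
writeScanConfig <- function(cfg, path) {
  sl <- methods::slotNames(cfg)
  x <- stats::setNames(lapply(sl, function(s) methods::slot(cfg, s)), sl)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Equidistant volume grid
#'
#' n equidistant volumes inclusive of both endpoints (n = 1 returns vMin).
#'
#' @param vMin,vMax volume range (l), positive.
#' @param n number of volumes.
#' @return numeric vector of volumes.
#' @examples
#' volumeGrid(5e-16, 1e-13, 300)[c(1, 300)]
#' @export
volumeGrid <- function(vMin, vMax, n) {
  if (vMin <= 0 || vMax <= 0) stop("volumes must be positive")
  if (n == 1) return(vMin)
  if (vMin >= vMax) stop("need vMin < vMax")
  seq(vMin, vMax, length.out = n)
}

## one (volume, replicate) task: fused SSA + measurement at the finest
## candidate frequency; everything downstream is deterministic.
.scan_task <- function(net, arrs, init_counts, cfg, vi, ri, track_idx) {
  set.seed(deriveSeed(cfg@masterSeed, vi, ri))
  Fmax <- max(cfg@candidateF)
  n_samples <- floor(cfg@tPSD * Fmax)
  a <- arrs[[vi]]
  .ssa_scan_cpp(a$r1, a$r2, a$homo, a$cj, a$S,
                as.numeric(init_counts[[vi]]), cfg@tStats, cfg@tStats,
                cfg@tPSD, track_idx - 1L, 1 / Fmax, n_samples, 5e8)
}

## spectral pipeline for one species at one volume from replicate sample
## vectors (columns at the finest frequency)
.species_spectrum <- function(samp_list, var_psd, cfg) {
  Fmax <- max(cfg@candidateF)
  strides <- Fmax / cfg@candidateF
  if (any(abs(strides - round(strides)) > 1e-9))
    stop("candidate frequencies must divide the largest candidate")
  strides <- as.integer(round(strides))
  # captured-power selection on the first replicate
  x1 <- samp_list[[1]]
  n <- length(x1)
  frac <- vapply(strides, function(s) {
    xs <- x1[seq(1, n, by = s)]
    v <- mean((xs - mean(xs))^2)
    if (var_psd <= 0) 1 else v / var_psd
  }, 0)
  sel <- which(frac >= cfg@powerThreshold)
  if (!length(sel))
    return(list(ok = FALSE, reason = paste0(
      "no candidate frequency captures ", cfg@powerThreshold,
      " of the signal power (achieved ",
      paste(signif(frac, 3), collapse = ", "), ")")))
  sel <- sel[1]
  Fsel <- cfg@candidateF[sel]
  targetF <- min(cfg@candidateF)
  psds <- lapply(samp_list, function(x) {
    sig <- UniformSignal(x[seq(1, length(x), by = strides[sel])], 1 / Fsel)
    if (Fsel > targetF) sig <- decimate(sig, as.integer(Fsel / targetF))
    nv <- length(sig@values)
    if (nv %% 2 == 1) sig@values <- sig@values[-nv]
    periodogramPSD(sig, window = "rectangular", demean = TRUE)
  })
  f1_raw <- psds[[1]]@freqs[1]   # fundamental frequency of the raw grid
  avg <- smoothBins(ensembleAverage(psds), cfg@smoothingM)
  sl <- tryCatch(
    loglogSlope(avg, cfg@slopeBand[1] * f1_raw,
                max(avg@freqs) / cfg@slopeBand[2]),
    error = function(e) c(slope = NA_real_, stderr = NA_real_))
  list(ok = TRUE, psd = avg, slope = sl, sampleF = Fsel)
}

#' Run a volume scan
#'
#' The full pipeline: deterministic ODE steady state, per-volume count
#' discretization, replicate SSA realizations per volume (each on its own
#' reproducible RNG substream), per-species sampling-frequency selection by
#' the 95 percent captured-power rule, decimation to the common analysis
#' band, smoothed ensemble-averaged periodogram PSDs with log-log slopes,
#' and exact time-weighted CV and frequency-of-change statistics. The result
#' is a pure function of (network file, config) - in particular it does not
#' depend on \code{nWorkers} or task scheduling, because every (volume,
#' replicate) task seeds its own stream and aggregation is a deterministic
#' reduce in index order.
#'
#' Per-cell failures (steady-state or sampling-frequency selection) are
#' recorded (NA statistics, reason in the provenance) and do not abort the
#' scan.
#'
#' @param cfg a \linkS4class{ScanConfig}.
#' @return A \linkS4class{ScanResult}.
#' @export
runScan <- function(cfg) {
  methods::validObject(cfg)
  net <- loadNetwork(cfg@networkPath)
  ss <- findSteadyState(net)
  vols <- volumeGrid(cfg@vMin, cfg@vMax, cfg@nVolumes)
  vsp <- variableSpecies(net)
  psd_sp <- if (length(cfg@psdSpecies)) cfg@psdSpecies else vsp
  bad <- setdiff(psd_sp, vsp)
  if (length(bad)) stop("unknown/constant psdSpecies: ",
                        paste(bad, collapse = ", "))
  all_sp <- speciesNames(net)
  track_idx <- match(psd_sp, all_sp)

  ctxs <- lapply(vols, VolumeContext)
  arrs <- lapply(ctxs, function(cx) .net_arrays(net, cx))
  init_counts <- lapply(ctxs, function(cx) concentrationsToCounts(ss, cx))

  tasks <- expand.grid(ri = seq_len(cfg@replicates),
                       vi = seq_len(cfg@nVolumes))
  runner <- function(i) .scan_task(net, arrs, init_counts, cfg,
                                   tasks$vi[i], tasks$ri[i], track_idx)
  res <- if (cfg@nWorkers > 1 && .Platform$OS.type == "unix")
    parallel::mclapply(seq_len(nrow(tasks)), runner,
                       mc.cores = cfg@nWorkers, mc.preschedule = TRUE)
  else lapply(seq_len(nrow(tasks)), runner)

  nV <- cfg@nVolumes
  vi_of <- tasks$vi
  first_rep <- match(seq_len(nV), vi_of)  # replicate 1 of each volume

  cv <- fc <- mc <- matrix(NA_real_, length(vsp), nV,
                           dimnames = list(vsp, signif(vols, 6)))
  vidx <- match(vsp, all_sp)
  for (v in seq_len(nV)) {
    r1 <- res[[first_rep[v]]]
    m <- r1$mean_stats[vidx]
    s <- sqrt(r1$var_stats[vidx])
    cv[, v] <- coefficientOfVariation(m, s)
    fc[, v] <- r1$fc[vidx]
    mc[, v] <- m
  }

  psd_maps <- stats::setNames(
    replicate(length(psd_sp), vector("list", nV), simplify = FALSE), psd_sp)
  slopes <- data.frame()
  failures <- list()
  for (v in seq_len(nV)) {
    reps <- which(vi_of == v)
    for (si in seq_along(psd_sp)) {
      samp <- lapply(reps, function(i) res[[i]]$samples[, si])
      vpsd <- res[[reps[1]]]$var_psd[track_idx[si]]
      out <- .species_spectrum(samp, vpsd, cfg)
      if (!out$ok) {
        failures[[length(failures) + 1]] <-
          list(species = psd_sp[si], volume = vols[v], reason = out$reason)
        slopes <- rbind(slopes, data.frame(
          species = psd_sp[si], volume = vols[v], slope = NA_real_,
          stderr = NA_real_, sampleF = NA_real_))
      } else {
        psd_maps[[si]][[v]] <- out$psd
        slopes <- rbind(slopes, data.frame(
          species = psd_sp[si], volume = vols[v],
          slope = out$slope[["slope"]], stderr = out$slope[["stderr"]],
          sampleF = out$sampleF))
      }
    }
  }

  ## heat-map row convention: species ascending by steady-state concentration
  ord <- order(ss[vsp], match(vsp, all_sp))
  cv <- cv[ord, , drop = FALSE]
  fc <- fc[ord, , drop = FALSE]
  mc <- mc[ord, , drop = FALSE]

  new("ScanResult", config = cfg, volumes = vols,
      steadyState = stats::setNames(as.numeric(ss), names(ss)),
      cv = cv, fc = fc, meanCounts = mc, psd = psd_maps, slopes = slopes,
      provenance = list(masterSeed = cfg@masterSeed,
                        packageVersion =
                          as.character(utils::packageVersion("brnnoise")),
                        failures = failures))
}

setMethod("show", "ScanResult", function(object) {
  cat(sprintf(
    "ScanResult: %d volumes in [%g, %g] l, %d species, %d replicate(s)\n",
    length(object@volumes), min(object@volumes), max(object@volumes),
    nrow(object@cv), object@config@replicates))
})

#' Export a scan result
#'
#' Writes cv.csv and fc.csv (raw statistics, species rows ascending by
#' steady-state concentration, volume columns, undefined cells as NA),
#' cv_normalized.csv / fc_normalized.csv (divided by the per-matrix maximum,
#' the heat-map scaling), steady_state.csv, slopes.csv, one PSD heat-map CSV
#' per spectral species (rows = volumes, columns = frequency bins), and
#' provenance.json. Re-exporting over the same directory is idempotent.
#'
#' @param result a \linkS4class{ScanResult}.
#' @param outDir output directory (created if missing).
#' @return character vector of written paths (the manifest), invisibly.
#' @export
exportScan <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  manifest <- character(0)
  wm <- function(m, f) {
    utils::write.csv(m, p(f), row.names = TRUE, na = "NA")
    manifest <<- c(manifest, p(f))
  }
  wm(result@cv, "cv.csv")
  wm(result@fc, "fc.csv")
  wm(normalizeByMax(result@cv), "cv_normalized.csv")
  wm(normalizeByMax(result@fc), "fc_normalized.csv")
  writeSteadyState(result@steadyState, p("steady_state.csv"))
  manifest <- c(manifest, p("steady_state.csv"))
  utils::write.csv(result@slopes, p("slopes.csv"), row.names = FALSE)
  manifest <- c(manifest, p("slopes.csv"))
  for (sp in names(result@psd)) {
    rows <- result@psd[[sp]]
    ok <- !vapply(rows, is.null, TRUE)
    if (!any(ok)) next
    f0 <- rows[[which(ok)[1]]]@freqs
    m <- t(vapply(seq_along(rows), function(v)
      if (ok[v]) rows[[v]]@power else rep(NA_real_, length(f0)),
      numeric(length(f0))))
    rownames(m) <- signif(result@volumes, 6)
    colnames(m) <- signif(f0, 6)
    fn <- paste0("psd_", gsub("[^A-Za-z0-9]+", "_", sp), ".csv")
    wm(m, fn)
  }
  jsonlite::write_json(result@provenance, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- c(manifest, p("provenance.json"))
  invisible(manifest)
}
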