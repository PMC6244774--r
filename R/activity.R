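# Region-level oscillatory activity: broadband power per cortical parcel,
# tumor-mask dilation, atlas overlap, and the three activity scores
# (peritumor, global, non-tumor) with cohort- or reference-based z-scoring.

#' Construct a labeled atlas volume
#'
#' @param labels 3D integer array; 0 is background, 1..R are region labels.
#' @param voxel_size_mm Voxel edge lengths, length 3 (mm).
#' @return Object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size_mm = c(1, 1, 1)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers")
  }
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "labeled_volume")
}

#' Construct a binary mask volume
#'
#' @param mask 3D array coercible to logical, aligned to its atlas grid.
#' @param voxel_size_mm Voxel edge lengths, length 3 (mm).
#' @return Object of class `mask_volume`.
#' @export
mask_volume <- function(mask, voxel_size_mm = c(1, 1, 1)) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  m <- array(mask != 0, dim(mask))
  if (!any(m)) stop("mask has no foreground voxels")
  structure(list(mask = m, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "mask_volume")
}

#' Read a volume from a NIfTI file
#'
#' Thin wrapper over \pkg{RNifti} returning a [labeled_volume()] or
#' [mask_volume()].
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param as `"atlas"` or `"mask"`.
#' @return A `labeled_volume` or `mask_volume`.
#' @export
read_volume <- function(path, as = c("atlas", "mask")) {
  as <- match.arg(as)
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (as == "atlas") labeled_volume(round(arr), vox) else
    mask_volume(arr != 0, vox)
}

#' Write a volume to a NIfTI file
#'
#' @param volume A `labeled_volume` or `mask_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI volumes requires the RNifti package")
  }
  arr <- if (inherits(volume, "labeled_volume")) volume$labels else
    volume$mask * 1L
  img <- RNifti::asNifti(arr, pixdim = volume$voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Band-integrated power of a signal (Welch estimate)
#'
#' Estimates the power spectral density by Welch's method — the signal is
#' split into segments (default 4 s) with 50% overlap, each demeaned,
#' Hann-tapered and periodogram-transformed, and the modified periodograms
#' are averaged — then integrates the one-sided PSD over the requested
#' frequency band. For a unit-amplitude sinusoid inside the band the result
#' is about 0.5 (amplitude squared over two); for white noise over the full
#' Nyquist range it is about the signal variance (Parseval).
#'
#' @param signal Numeric vector.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param band_hz Length-2 band limits (Hz); upper limit at most Nyquist.
#' @param segment_s Welch segment length in seconds (default 4; capped at
#'   the signal duration).
#' @return Band power (signal units squared), nonnegative scalar.
#' @export
band_power <- function(signal, sampling_rate_hz, band_hz = c(0.5, 48),
                       segment_s = 4) {
  signal <- as.numeric(signal)
  fs <- sampling_rate_hz
  if (length(band_hz) != 2L || band_hz[1] < 0 || band_hz[2] <= band_hz[1]) {
    stop("band_hz must be increasing and nonnegative")
  }
  if (band_hz[2] > fs / 2 + 1e-9) {
    stop("band upper limit exceeds the Nyquist frequency")
  }
  nseg <- min(length(signal), max(8L, round(segment_s * fs)))
  if (length(signal) < 8L) stop("signal too short for a PSD window")
  step <- max(1L, floor(nseg / 2)) # 50% overlap
  starts <- seq(1L, length(signal) - nseg + 1L, by = step)
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  u <- sum(hann^2) # window power normalisation
  psd <- rep(0, nseg)
  for (s in starts) {
    seg <- signal[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * hann
    psd <- psd + Mod(stats::fft(seg))^2
  }
  psd <- psd / (length(starts) * u * fs)
  freqs <- (seq_len(nseg) - 1) * fs / nseg
  # fold to one-sided
  half <- floor(nseg / 2) + 1L
  onesided <- psd[seq_len(half)]
  if (nseg %% 2 == 0) {
    onesided[2:(half - 1L)] <- onesided[2:(half - 1L)] +
      rev(psd[(half + 1L):nseg])
  } else {
    onesided[2:half] <- onesided[2:half] + rev(psd[(half + 1L):nseg])
  }
  f1 <- freqs[seq_len(half)]
  sel <- f1 >= band_hz[1] & f1 <= band_hz[2]
  sum(onesided[sel]) * fs / nseg
}

#' Broadband power for every region of a patient
#'
#' @param signals Matrix (time x regions) or list of per-region signals.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param band_hz Band limits (Hz), default 0.5-48.
#' @param patient_id Optional identifier carried through.
#' @return Object of class `region_power`: `patient_id`, `power` (length-R
#'   nonnegative vector), `band_hz`, `sampling_rate_hz`.
#' @export
region_power <- function(signals, sampling_rate_hz, band_hz = c(0.5, 48),
                         patient_id = NA_character_) {
  if (is.matrix(signals)) {
    signals <- lapply(seq_len(ncol(signals)), function(j) signals[, j])
  }
  p <- vapply(signals, band_power, numeric(1),
              sampling_rate_hz = sampling_rate_hz, band_hz = band_hz)
  structure(list(patient_id = patient_id, power = unname(p),
                 band_hz = band_hz, sampling_rate_hz = sampling_rate_hz),
            class = "region_power")
}

#' Dilate a binary mask
#'
#' Binary morphological dilation with a 3x3x3 box structuring element (the
#' 26-connected neighborhood plus centre), applied `iterations` times. The
#' output always contains the input.
#'
#' @param mask A `mask_volume`.
#' @param iterations Positive integer number of dilation passes (the tumor
#'   masks in this pipeline are dilated twice).
#' @return The dilated `mask_volume`.
#' @export
dilate_mask <- function(mask, iterations = 2L) {
  if (!inherits(mask, "mask_volume")) stop("mask must be a mask_volume")
  if (iterations < 1L || iterations != round(iterations)) {
    stop("iterations must be a positive integer")
  }
  m <- mask$mask
  dims <- dim(m)
  for (it in seq_len(iterations)) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sx <- .shift_range(dims[1], dx)
      sy <- .shift_range(dims[2], dy)
      sz <- .shift_range(dims[3], dz)
      out[sx$to, sy$to, sz$to] <-
        out[sx$to, sy$to, sz$to] | m[sx$from, sy$from, sz$from]
    }
    m <- out
  }
  mask_volume(m, mask$voxel_size_mm)
}

.shift_range <- function(n, d) {
  if (d >= 0) list(from = seq_len(n - d), to = seq_len(n - d) + d)
  else list(from = seq_len(n + d) - d, to = seq_len(n + d))
}

#' Atlas regions overlapping a mask
#'
#' A region is peritumor if at least `min_voxels` of its voxels (default 1:
#' any overlap) lie inside the dilated tumor mask.
#'
#' @param atlas A `labeled_volume`.
#' @param mask A `mask_volume` on the same grid (typically the dilated
#'   tumor mask).
#' @param min_voxels Minimal overlapping voxel count for inclusion.
#' @return Increasing integer vector of region labels. A mask that touches
#'   only background yields an empty set with a warning.
#' @export
peritumor_regions <- function(atlas, mask, min_voxels = 1L) {
  if (!identical(dim(atlas$labels), dim(mask$mask))) {
    stop("atlas and mask grids differ in shape")
  }
  labs <- atlas$labels[mask$mask]
  labs <- labs[labs > 0L]
  if (length(labs) == 0L) {
    warning("mask overlaps no atlas region")
    return(integer(0))
  }
  counts <- table(labs)
  sort(as.integer(names(counts)[counts >= min_voxels]))
}

#' Peritumor, global and non-tumor activity of one patient
#'
#' Averages region power three ways: over the peritumor set (regions
#' overlapping the dilated tumor mask), over all R regions (global), and
#' over the complement of the peritumor set (non-tumor). The three means
#' satisfy the exact identity
#' `global * R = k * peritumor + (R - k) * nontumor` with `k` the peritumor
#' set size. When the peritumor set covers every region the non-tumor mean
#' is undefined (`NaN`).
#'
#' @param power A `region_power` or plain nonnegative numeric vector.
#' @param peri Integer vector of peritumor region labels (nonempty, within
#'   1..R).
#' @return Object of class `oba_measures` with `patient_id`,
#'   `peritumor_raw`, `global_raw`, `nontumor_raw` and
#'   `peritumor_region_ids`. The z-score fields are filled cohort-wide by
#'   [oba_zscores()].
#' @export
compute_oba <- function(power, peri) {
  pid <- NA_character_
  if (inherits(power, "region_power")) {
    pid <- power$patient_id
    power <- power$power
  }
  power <- as.numeric(power)
  r <- length(power)
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("region power must be finite and nonnegative")
  }
  peri <- sort(unique(as.integer(peri)))
  if (length(peri) == 0L) {
    stop("tumor mask overlaps no atlas region; peritumor set is empty")
  }
  if (any(peri < 1L) || any(peri > r)) stop("peritumor labels outside 1..R")
  nonperi <- setdiff(seq_len(r), peri)
  structure(
    list(patient_id = pid,
         peritumor_raw = mean(power[peri]),
         global_raw = mean(power),
         nontumor_raw = if (length(nonperi)) mean(power[nonperi]) else NaN,
         peritumor_z = NA_real_, global_z = NA_real_, nontumor_z = NA_real_,
         global_z_ref = NA_real_,
         peritumor_region_ids = peri),
    class = "oba_measures"
  )
}

#' Cohort-based z-scores
#'
#' Centers and scales by the cohort mean and sample standard deviation
#' (divisor n - 1), so the output has mean 0 and SD 1 exactly.
#'
#' @param values Numeric vector, length >= 2, nonzero variance.
#' @return Z-scores of the same length.
#' @export
zscore_cohort <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance; z-scores undefined")
  (values - mean(values)) / s
}

#' Reference-based z-scores
#'
#' Standardises against an external reference distribution (e.g. healthy
#' controls) instead of the cohort itself.
#'
#' @param values Numeric vector.
#' @param ref_mean Reference mean.
#' @param ref_sd Reference standard deviation, strictly positive.
#' @return `(values - ref_mean) / ref_sd`.
#' @export
zscore_reference <- function(values, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) stop("ref_sd must be positive")
  (as.numeric(values) - ref_mean) / ref_sd
}

#' Assemble the per-patient activity table for a cohort
#'
#' Takes one `oba_measures` per patient, z-scores each raw measure across
#' the cohort, and optionally adds reference-based z-scores of the global
#' measure.
#'
#' @param measures List of `oba_measures`.
#' @param ref_mean,ref_sd Optional reference mean/SD for `global_z_ref`.
#' @return `data.frame` with raw and z-scored peritumor, global and
#'   non-tumor activity per patient.
#' @export
oba_zscores <- function(measures, ref_mean = NULL, ref_sd = NULL) {
  stopifnot(length(measures) >= 2L)
  get <- function(f) vapply(measures, function(m) m[[f]], numeric(1))
  # a patient whose peritumor set covers every region has no non-tumor
  # measure; z-score the rest and leave that entry missing
  zna <- function(x) {
    ok <- is.finite(x)
    z <- rep(NA_real_, length(x))
    z[ok] <- zscore_cohort(x[ok])
    z
  }
  out <- data.frame(
    patient_id = vapply(measures, function(m) m$patient_id, character(1)),
    peritumor_raw = get("peritumor_raw"),
    global_raw = get("global_raw"),
    nontumor_raw = get("nontumor_raw"),
    peritumor_z = zna(get("peritumor_raw")),
    global_z = zna(get("global_raw")),
    nontumor_z = zna(get("nontumor_raw")),
    row.names = NULL
  )
  if (!is.null(ref_mean) && !is.null(ref_sd)) {
    out$global_z_ref <- zscore_reference(out$global_raw, ref_mean, ref_sd)
  }
  out
}
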