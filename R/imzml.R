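# Minimal imzML (processed mode, centroided) reader/writer.
# The .imzML part is mzML-flavoured XML; the .ibd part holds the binary
# arrays, addressed by external offset/length cvParams. Only the subset of
# the standard needed for peak-picked data is supported.

CV_PROCESSED <- "IMS:1000031"
CV_CONTINUOUS <- "IMS:1000030"
CV_POS_X <- "IMS:1000050"
CV_POS_Y <- "IMS:1000051"
CV_MZ_ARRAY <- "MS:1000514"
CV_INT_ARRAY <- "MS:1000515"
CV_F64 <- "MS:1000523"
CV_F32 <- "MS:1000521"
CV_EXT_OFFSET <- "IMS:1000102"
CV_EXT_LENGTH <- "IMS:1000103"

ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Read a processed-mode imzML file into an MSI run
#'
#' Reads centroided spectra from an imzML/ibd pair, pools the observed peak
#' m/z values across all spectra, merges them into a shared feature axis by
#' single-linkage clustering within a ppm tolerance, and returns a
#' pixel-by-feature matrix with absent peaks stored as zero.
#'
#' @param path Path to the `.imzML` XML file (the `.ibd` binary must sit next
#'   to it with the same stem).
#' @param tol_ppm Peak-binning tolerance in ppm used to form the feature axis.
#' @param run_id Run identifier; defaults to the file stem.
#' @return An [msi_run()].
#' @export
read_imzml <- function(path, tol_ppm = 5, run_id = NULL) {
  if (is.null(run_id)) run_id <- sub("\\.imzML$", "", basename(path),
                                     ignore.case = TRUE)
  doc <- xml2::read_xml(path)       # malformed XML errors here
  xml2::xml_ns_strip(doc)

  accessions <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//fileDescription//cvParam"), "accession")
  if (CV_CONTINUOUS %in% accessions) {
    stop("unsupported imzML mode 'continuous': only processed-mode ",
         "(centroided) files are supported")
  }
  if (!CV_PROCESSED %in% accessions) {
    stop("imzML file does not declare processed mode")
  }

  con <- file(ibd_path(path), "rb")
  on.exit(close(con))

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (length(spectra) == 0L) stop("imzML file contains no spectra")
  peaks <- vector("list", length(spectra))
  coords <- matrix(0L, length(spectra), 2L)
  for (s in seq_along(spectra)) {
    sp <- spectra[[s]]
    px <- xml2::xml_attr(xml2::xml_find_first(
      sp, sprintf(".//cvParam[@accession='%s']", CV_POS_X)), "value")
    py <- xml2::xml_attr(xml2::xml_find_first(
      sp, sprintf(".//cvParam[@accession='%s']", CV_POS_Y)), "value")
    coords[s, ] <- c(as.integer(px), as.integer(py))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mzv <- NULL; intv <- NULL
    for (arr in arrays) {
      acc <- xml2::xml_attr(xml2::xml_find_all(arr, ".//cvParam"), "accession")
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        arr, sprintf(".//cvParam[@accession='%s']", CV_EXT_OFFSET)), "value"))
      len <- as.integer(xml2::xml_attr(xml2::xml_find_first(
        arr, sprintf(".//cvParam[@accession='%s']", CV_EXT_LENGTH)), "value"))
      bytes <- if (CV_F64 %in% acc) 8L else 4L
      seek(con, where = off, origin = "start")
      vals <- readBin(con, "double", n = len, size = bytes, endian = "little")
      if (CV_MZ_ARRAY %in% acc) mzv <- vals
      if (CV_INT_ARRAY %in% acc) intv <- vals
    }
    if (is.null(mzv) || is.null(intv) || length(mzv) != length(intv)) {
      stop("spectrum ", s, ": missing or mismatched m/z / intensity arrays")
    }
    o <- order(mzv)                 # spectra need not be stored sorted
    peaks[[s]] <- cbind(mz = mzv[o], intensity = intv[o])
  }

  all_mz <- unlist(lapply(peaks, function(p) p[, 1]))
  all_wt <- unlist(lapply(peaks, function(p) p[, 2]))
  cl <- cluster_mz(all_mz, tol_ppm)
  axis <- cluster_centers(all_mz, all_wt, cl$cluster)
  mat <- matrix(0, length(spectra), length(axis))
  idx_start <- 0L
  for (s in seq_along(peaks)) {
    np <- nrow(peaks[[s]])
    if (np > 0L) {
      cols <- cl$cluster[idx_start + seq_len(np)]
      for (p in seq_len(np)) {      # sum if two peaks of one pixel share a bin
        mat[s, cols[p]] <- mat[s, cols[p]] + peaks[[s]][p, 2]
      }
    }
    idx_start <- idx_start + np
  }
  msi_run(run_id, coords, axis, mat)
}

# Single-linkage clustering of sorted-pooled m/z values within a ppm
# tolerance: adjacent values are chained when their gap is within tol.
# Returns cluster ids in the order of the input values.
cluster_mz <- function(mz, tol_ppm) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  o <- order(mz)
  s <- mz[o]
  n <- length(s)
  cl_sorted <- integer(n)
  if (n > 0) {
    cl_sorted[1] <- 1L
    if (n > 1) {
      gaps_ppm <- diff(s) / s[-n] * 1e6
      cl_sorted[-1] <- 1L + cumsum(gaps_ppm > tol_ppm)
    }
  }
  cluster <- integer(n)
  cluster[o] <- cl_sorted
  widths_ppm <- vapply(split(s, cl_sorted), function(v) {
    (max(v) - min(v)) / min(v) * 1e6
  }, numeric(1))
  list(cluster = cluster, widths_ppm = unname(widths_ppm))
}

# Intensity-weighted mean m/z per cluster (plain mean when weights are 0).
cluster_centers <- function(mz, wt, cluster) {
  centers <- vapply(split(seq_along(mz), cluster), function(ii) {
    w <- wt[ii]
    if (sum(w) <= 0) mean(mz[ii]) else sum(mz[ii] * w) / sum(w)
  }, numeric(1))
  unname(centers)
}

#' Combine runs onto a shared feature axis
#'
#' Pools the per-run m/z axes and merges features by single-linkage clustering
#' within a ppm tolerance. Each merged feature is labelled with the
#' intensity-weighted mean m/z of its members; features absent from a run are
#' zero-padded there. A merge report (one row per merged feature) is attached
#' as attribute `"merge_report"`, with a warning recorded for any cluster
#' wider than `2 * tol_ppm`.
#'
#' @param runs List of [msi_run()] objects.
#' @param tol_ppm Merge tolerance in ppm (> 0). No default is supplied: the
#'   appropriate value depends on the mass analyser.
#' @param design Optional design data frame passed to [msi_experiment()];
#'   defaults to a single-condition placeholder design.
#' @return An [msi_experiment()] on the shared axis.
#' @export
combine_runs <- function(runs, tol_ppm, design = NULL) {
  stopifnot(length(runs) >= 1L)
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  mz_all <- unlist(lapply(runs, function(r) r$mz))
  wt_all <- unlist(lapply(runs, function(r) colSums(r$intensities)))
  cl <- cluster_mz(mz_all, tol_ppm)
  axis <- cluster_centers(mz_all, wt_all, cl$cluster)
  k <- length(axis)
  wide <- which(cl$widths_ppm > 2 * tol_ppm)
  report <- data.frame(feature = seq_len(k), mz = axis,
                       n_members = as.integer(table(cl$cluster)),
                       width_ppm = cl$widths_ppm,
                       wide = seq_len(k) %in% wide)
  if (length(wide) > 0L) {
    warning(length(wide), " merged feature(s) wider than 2*tol_ppm; ",
            "see the merge report")
  }
  offset <- 0L
  new_runs <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    nf <- length(r$mz)
    cols <- cl$cluster[offset + seq_len(nf)]
    offset <- offset + nf
    mat <- matrix(0, n_pixels(r), k)
    for (f in seq_len(nf)) {        # sum if two run features merge (rare)
      mat[, cols[f]] <- mat[, cols[f]] + r$intensities[, f]
    }
    new_runs[[i]] <- msi_run(r$run_id, r$coords, axis, mat)
  }
  if (is.null(design)) {
    design <- data.frame(run_id = vapply(new_runs, `[[`, character(1), "run_id"),
                         subject = paste0("subj", seq_along(new_runs)),
                         condition = "cond1", tissue = "tissue1")
  }
  exp <- msi_experiment(new_runs, design)
  attr(exp, "merge_report") <- report
  exp
}

#' Write a fixture imzML/ibd pair for one run
#'
#' Emits a minimal standard-compliant processed-mode file: 64-bit m/z arrays,
#' 32-bit intensity arrays, one spectrum per pixel. Zero intensities are
#' written as absent peaks (the sparse convention), so reading the file back
#' reproduces the zero-filled matrix.
#'
#' @param run An [msi_run()].
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param shuffle_mz If `TRUE`, each spectrum's peak list is written in
#'   reverse m/z order (exercises reader re-sorting); default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(run, path, shuffle_mz = FALSE) {
  ibd <- ibd_path(path)
  con <- file(ibd, "wb")
  uuid <- as.raw(rep(0L, 16L))
  writeBin(uuid, con)
  offset <- 16
  specs <- list()
  for (s in seq_len(n_pixels(run))) {
    ints <- run$intensities[s, ]
    keep <- which(ints > 0)
    mzv <- run$mz[keep]; iv <- ints[keep]
    if (shuffle_mz && length(keep) > 1L) { mzv <- rev(mzv); iv <- rev(iv) }
    writeBin(mzv, con, size = 8L, endian = "little")
    mz_off <- offset; offset <- offset + 8 * length(mzv)
    writeBin(iv, con, size = 4L, endian = "little")
    int_off <- offset; offset <- offset + 4 * length(iv)
    specs[[s]] <- list(n = length(keep), mz_off = mz_off, int_off = int_off,
                       x = run$coords[s, 1], y = run$coords[s, 2])
  }
  close(con)

  cv <- function(acc, name, value = NULL) {
    v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
    ref <- if (startsWith(acc, "IMS")) "IMS" else "MS"
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>',
            ref, acc, name, v)
  }
  spec_xml <- vapply(seq_along(specs), function(s) {
    sp <- specs[[s]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              s - 1L, s, sp$n),
      '<scanList count="1"><scan>',
      cv(CV_POS_X, "position x", sp$x),
      cv(CV_POS_Y, "position y", sp$y),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      cv(CV_MZ_ARRAY, "m/z array"), cv(CV_F64, "64-bit float"),
      cv(CV_EXT_OFFSET, "external offset", sprintf("%.0f", sp$mz_off)),
      cv(CV_EXT_LENGTH, "external array length", sp$n),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      cv(CV_INT_ARRAY, "intensity array"), cv(CV_F32, "32-bit float"),
      cv(CV_EXT_OFFSET, "external offset", sprintf("%.0f", sp$int_off)),
      cv(CV_EXT_LENGTH, "external array length", sp$n),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    cv(CV_PROCESSED, "processed"),
    cv("MS:1000127", "centroid spectrum"),
    '</fileContent></fileDescription>',
    '<run id="', run$run_id, '">',
    sprintf('<spectrumList count="%d">', length(specs)),
    paste0(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Write a results table as deterministic delimited text
#'
#' Columns keep their given order; rows are sorted by the `mz` column when
#' present so repeated runs produce byte-identical files.
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  if ("mz" %in% names(table) && nrow(table) > 1L) {
    table <- table[order(table$mz), , drop = FALSE]
  }
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an ROI mask as a CSV label grid
#'
#' Plain-text alternative to image masks: one row per pixel with columns
#' `x`, `y`, `label`, plus the mask source and consumed features in comment
#' headers.
#'
#' @param mask An [roi_mask()].
#' @param coords Pixel coordinates of the owning run.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, coords, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# source: %s", mask$source),
               sprintf("# features_consumed: %s",
                       paste(mask$features_consumed, collapse = ";"))), con)
  utils::write.csv(data.frame(x = coords[, 1], y = coords[, 2],
                              label = mask$labels),
                   con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_mask_csv
#' @param path Path of a CSV written by [write_mask_csv()].
#' @export
read_mask_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  src <- sub("^# source: ", "", hdr[1])
  fc <- sub("^# features_consumed: ", "", hdr[2])
  fc <- if (nzchar(fc)) as.numeric(strsplit(fc, ";")[[1]]) else numeric(0)
  df <- utils::read.csv(path, comment.char = "#")
  m <- roi_mask(df$label, source = src, features_consumed = fc)
  attr(m, "coords") <- cbind(x = df$x, y = df$y)
  m
}
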