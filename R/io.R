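# Reading and writing calibrated TIFF stacks, label masks and result tables.
#
# Calibration on read is resolved with the precedence
#   explicit override > OME-XML description > ImageJ-style description >
#   TIFF resolution tags > JSON calibration sidecar,
# and its absence is an error: micrometer lengths are the headline output,
# so a silent pixel-size default would be worse than failing.
# The package's own writer stores voxel sizes and axis counts in a JSON
# sidecar (`<file>.calibration.json`) next to the TIFF, because the linked
# libtiff interface does not expose description/resolution tags on write.

sidecar_path <- function(path) paste0(path, ".calibration.json")

# ---- metadata parsing -------------------------------------------------------

parse_imagej_description <- function(desc) {
  if (is.null(desc) || !grepl("^ImageJ=", desc)) return(NULL)
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2]
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k) if (k %in% names(vals)) suppressWarnings(as.numeric(vals[[k]])) else NA_real_
  list(source = "imagej",
       n_c = num("channels"), n_z = num("slices"), n_t = num("frames"),
       n_images = num("images"),
       dz = num("spacing"), frame_interval = num("finterval"),
       unit = if ("unit" %in% names(vals)) vals[["unit"]] else NA_character_,
       order = "XYCZT")
}

parse_ome_description <- function(desc) {
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  a <- function(nm) {
    v <- xml2::xml_attr(px, nm)
    if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  ord <- xml2::xml_attr(px, "DimensionOrder")
  list(source = "ome",
       n_c = a("SizeC"), n_z = a("SizeZ"), n_t = a("SizeT"),
       dx = a("PhysicalSizeX"), dy = a("PhysicalSizeY"),
       dz = a("PhysicalSizeZ"), frame_interval = a("TimeIncrement"),
       unit = "micron",
       order = if (is.na(ord)) "XYCZT" else ord)
}

# lateral pixel size in um from TIFF resolution tags (pixels per unit)
resolution_tag_pixel_size <- function(attrs, unit_hint = NA_character_) {
  xr <- attrs$x.resolution
  if (is.null(xr) || !is.numeric(xr) || xr <= 0) return(NULL)
  yr <- if (!is.null(attrs$y.resolution)) attrs$y.resolution else xr
  ru <- if (!is.null(attrs$resolution.unit)) attrs$resolution.unit else "none"
  per_um <- function(r, u) {
    switch(u,
           "inch" = r / 25400, "cm" = r / 10000,
           "um" = r, "micron" = r, "µm" = r,
           NULL)
  }
  u <- if (ru %in% c("inch", "cm")) ru else unit_hint
  if (is.na(u) || is.null(u)) return(NULL)
  rx <- per_um(xr, u); ry <- per_um(yr, u)
  if (is.null(rx) || is.null(ry)) return(NULL)
  list(dx = 1 / rx, dy = 1 / ry)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
           error = function(e) NULL)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

# page index (1-based) for channel/slice/frame given a dimension order
page_index <- function(c, z, t, n_c, n_z, n_t, order = "XYCZT") {
  ax <- strsplit(sub("^XY", "", order), "")[[1]]
  sizes <- c(C = unname(n_c), Z = unname(n_z), T = unname(n_t))
  idx <- c(C = unname(c), Z = unname(z), T = unname(t)) - 1L
  p <- 0L; mult <- 1L
  for (a in ax) {
    p <- p + idx[[a]] * mult
    mult <- mult * sizes[[a]]
  }
  p + 1L
}

# ---- stacks -----------------------------------------------------------------

#' Read a calibrated multi-channel z-stack from TIFF / OME-TIFF
#'
#' Axis layout and voxel calibration are taken from embedded metadata when
#' present (OME-XML, ImageJ hyperstack description, TIFF resolution tags) or
#' from the JSON calibration sidecar written by [write_stack()]. An explicit
#' `calibration_override` always wins; if no calibration can be resolved at
#' all, reading fails.
#'
#' @param path TIFF or OME-TIFF file.
#' @param marker_channel index of the segmentation channel.
#' @param calibration_override optional [calibration()] taking precedence
#'   over any file metadata.
#' @param n_channels,n_slices,n_frames optional explicit axis sizes for
#'   plain TIFFs without axis metadata. Without metadata and without these,
#'   a multi-page file is read as a single-channel z-stack; sizes that do
#'   not factor the page count are an error.
#' @param channel_names optional channel labels.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, marker_channel = 1L, calibration_override = NULL,
                       n_channels = NULL, n_slices = NULL, n_frames = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  attrs <- attributes(pages[[1]])
  # 32-bit pages are floats: the raw-integer path is meaningless for them,
  # so fall back to the normalized [0, 1] reading and undo the writer's
  # scaling (recorded in the sidecar) afterwards
  float_scale <- NULL
  if (!is.null(attrs$bits.per.sample) && attrs$bits.per.sample == 32) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    attrs <- attributes(pages[[1]])
    sc <- read_sidecar(path)
    float_scale <- if (!is.null(sc$scale)) sc$scale else 1
  }
  desc <- attrs$description
  meta <- parse_ome_description(desc)
  if (is.null(meta)) meta <- parse_imagej_description(desc)
  side <- read_sidecar(path)

  # per-page samples become channels for RGB-style pages
  pd <- dim(pages[[1]])
  samples <- if (length(pd) == 3) pd[3] else 1L
  ny <- pd[1]; nx <- pd[2]
  n_pages <- length(pages)

  get1 <- function(...) {
    for (v in list(...)) if (!is.null(v) && length(v) == 1 && !is.na(v))
      return(as.integer(v))
    NA_integer_
  }
  n_c <- get1(n_channels, meta$n_c, side$channels)
  n_z <- get1(n_slices, meta$n_z, side$slices)
  n_t <- get1(n_frames, meta$n_t, side$frames)

  if (samples > 1) {
    if (!is.na(n_c) && n_c != samples)
      stop("ambiguous axis order: per-page samples (", samples,
           ") conflict with declared channel count (", n_c, ")")
    n_c <- 1L # channels live in the sample axis, pages carry z/t
    if (is.na(n_z) && is.na(n_t)) { n_z <- n_pages; n_t <- 1L }
  }
  if (is.na(n_c)) n_c <- 1L
  if (is.na(n_t)) n_t <- 1L
  if (is.na(n_z)) {
    if (n_pages %% (n_c * n_t) != 0)
      stop("ambiguous axis order: ", n_pages, " pages cannot hold ",
           n_c, " channel(s) x ", n_t, " frame(s)")
    n_z <- n_pages %/% (n_c * n_t)
  }
  if (n_c * n_z * n_t != n_pages)
    stop("ambiguous axis order: channels x slices x frames (",
         n_c * n_z * n_t, ") != page count (", n_pages, ")")

  order <- if (!is.null(meta$order)) meta$order else "XYCZT"
  eff_c <- if (samples > 1) samples else n_c
  arr <- array(0, dim = c(n_t, eff_c, n_z, ny, nx))
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
    if (samples > 1) {
      pg <- pages[[page_index(1L, z, t, 1L, n_z, n_t, order)]]
      for (ch in seq_len(samples)) arr[t, ch, z, , ] <- pg[, , ch]
    } else {
      for (ch in seq_len(n_c))
        arr[t, ch, z, , ] <- pages[[page_index(ch, z, t, n_c, n_z, n_t, order)]]
    }
  }

  if (!is.null(float_scale)) arr <- arr * float_scale

  cal <- resolve_calibration(calibration_override, meta, attrs, side, n_z)
  if (is.null(channel_names)) {
    if (!is.null(side$channel_names) && length(side$channel_names) == eff_c)
      channel_names <- as.character(side$channel_names)
  }
  image_stack(arr, cal, channel_names = channel_names,
              marker_channel = marker_channel)
}

resolve_calibration <- function(override, meta, attrs, side, n_z) {
  if (!is.null(override)) {
    stopifnot(is_calibration(override))
    return(override)
  }
  dx <- dy <- dz <- fi <- NA_real_
  unit_hint <- if (!is.null(meta$unit)) meta$unit else NA_character_
  if (!is.null(meta)) {
    if (!is.null(meta$dx) && !is.na(meta$dx)) { dx <- meta$dx; dy <- meta$dy }
    if (!is.null(meta$dz)) dz <- meta$dz
    if (!is.null(meta$frame_interval)) fi <- meta$frame_interval
  }
  if (is.na(dx)) {
    res <- resolution_tag_pixel_size(attrs, unit_hint)
    if (!is.null(res)) { dx <- res$dx; dy <- res$dy }
  }
  if ((is.na(dx) || (is.na(dz) && n_z > 1)) && !is.null(side)) {
    if (is.na(dx) && !is.null(side$dx)) { dx <- side$dx; dy <- side$dy }
    if (is.na(dz) && !is.null(side$dz)) dz <- side$dz
    if (is.na(fi) && !is.null(side$frame_interval) &&
        !is.null(side$frame_interval)) fi <- side$frame_interval
  }
  if (is.na(dx))
    stop("missing calibration: no override, file metadata or sidecar found")
  if (is.na(dy)) dy <- dx
  if (is.na(dz)) {
    if (n_z > 1)
      stop("missing calibration: z spacing unknown for a multi-slice stack")
    dz <- dx # single slice: nominal isotropic voxel
  }
  calibration(dx = dx, dy = dy, dz = dz,
              frame_interval = if (is.null(fi)) NA_real_ else fi)
}

#' Write an image stack to TIFF with a calibration sidecar
#'
#' Pages are written channel-fastest, then slice, then frame (`XYCZT`).
#' Integer-valued data are stored as 8- or 16-bit, other data as 32-bit
#' float. Voxel sizes, frame interval and axis sizes go into
#' `<path>.calibration.json`, which [read_stack()] picks up.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(is_image_stack(stack))
  d <- stack_dim(stack)
  v <- stack$voxels
  maxv <- max(v)
  int_like <- all(v == round(v))
  if (int_like && maxv <= 255) {
    bits <- 8L; scale <- 255
  } else if (int_like && maxv <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    # float storage is limited to [0, 1]; normalize by the data maximum and
    # record the factor in the sidecar
    bits <- 32L; scale <- if (maxv > 0) maxv else 1
  }
  pages <- vector("list", d["t"] * d["c"] * d["z"])
  i <- 0L
  for (t in seq_len(d["t"])) for (z in seq_len(d["z"]))
    for (ch in seq_len(d["c"])) {
      i <- i + 1L
      pg <- v[t, ch, z, , ]
      dim(pg) <- d[4:5]
      pages[[page_index(ch, z, t, d["c"], d["z"], d["t"])]] <- pg / scale
    }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                 reduce = FALSE),
                 error = function(e) stop("cannot write TIFF: ", path, " (",
                                          conditionMessage(e), ")"))
  cal <- stack$calibration
  write_sidecar(path, list(
    kind = "stack", dx = cal$dx, dy = cal$dy, dz = cal$dz,
    frame_interval = if (is.na(cal$frame_interval)) NULL else cal$frame_interval,
    channels = unname(d["c"]), slices = unname(d["z"]), frames = unname(d["t"]),
    channel_names = stack$channel_names,
    marker_channel = stack$marker_channel, bits = bits,
    scale = if (bits == 32L) scale else NULL))
  invisible(path)
}

# ---- masks ------------------------------------------------------------------

#' Write a segmentation mask or label volume to TIFF
#'
#' Background is 0; objects keep their integer labels (a logical mask is
#' written as 0/1). Calibration goes into the JSON sidecar.
#'
#' @param mask a `segmentation_mask`, logical volume or integer label
#'   volume with dimensions `(z, y, x)`.
#' @param calibration a [calibration()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, calibration, path) {
  stopifnot(is_calibration(calibration))
  if (inherits(mask, "segmentation_mask")) mask <- mask$foreground
  if (is.logical(mask)) mask <- array(as.integer(mask), dim = dim(mask))
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (max(mask) > 65535) stop("more than 65535 labels not supported")
  d <- dim(mask)
  pages <- lapply(seq_len(d[1]), function(z) {
    pg <- mask[z, , ]
    dim(pg) <- d[2:3]
    pg / 65535
  })
  tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE),
           error = function(e) stop("cannot write TIFF: ", path, " (",
                                    conditionMessage(e), ")"))
  write_sidecar(path, list(kind = "labels", dx = calibration$dx,
                           dy = calibration$dy, dz = calibration$dz,
                           slices = d[1], channels = 1L, frames = 1L))
  invisible(path)
}

#' Read a label volume written by [write_mask()]
#'
#' @param path TIFF file.
#' @param calibration_override optional [calibration()].
#' @return List with integer array `labels` `(z, y, x)` and `calibration`.
#' @export
read_mask <- function(path, calibration_override = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])[1:2]
  labels <- array(0L, dim = c(length(pages), d2))
  for (z in seq_along(pages)) labels[z, , ] <- as.integer(pages[[z]])
  side <- read_sidecar(path)
  cal <- resolve_calibration(calibration_override, NULL,
                             attributes(pages[[1]]), side, length(pages))
  list(labels = labels, calibration = cal)
}

# ---- tables -----------------------------------------------------------------

#' Write the per-cilium results table to CSV
#'
#' One row per cilium with the stable column set: `id`, `n_voxels`,
#' `volume_um3`, centroid coordinates in micrometers, per-channel mean
#' intensities (`mean_int_1`, `mean_int_2`, ...), `length_um` (longest
#' skeleton geodesic), `total_skeleton_um` and `border_touching`. Objects
#' without a measured length get an empty length field and a warning.
#'
#' @param objects list of cilium objects (see [label_components()]).
#' @param path output CSV path.
#' @return The table, invisibly.
#' @export
write_object_table <- function(objects, path) {
  tab <- objects_to_table(objects)
  if (nrow(tab) > 0 && anyNA(tab$length_um))
    warning(sum(is.na(tab$length_um)),
            " object(s) lack a measured length; field left empty")
  tryCatch(utils::write.csv(tab, path, row.names = FALSE, na = ""),
           error = function(e) stop("cannot write table: ", path))
  invisible(tab)
}

#' Read a per-cilium results table written by [write_object_table()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_object_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a fluorescence trace table to CSV (long format)
#'
#' Columns: `frame`, `time_s`, `channel`, `value`, `stimulus_frame`.
#'
#' @param trace a [ts_trace()].
#' @param path output CSV path.
#' @return The table, invisibly.
#' @export
write_trace_table <- function(trace, path) {
  stopifnot(inherits(trace, "ts_trace"))
  v <- trace$values
  ch <- colnames(v)
  tab <- data.frame(
    frame = rep(seq_len(nrow(v)), times = ncol(v)),
    time_s = rep(trace$frame_times, times = ncol(v)),
    channel = rep(ch, each = nrow(v)),
    value = as.vector(v),
    stimulus_frame = trace$stimulus_frame)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(tab)
}

#' Read a trace table written by [write_trace_table()]
#'
#' @param path CSV path.
#' @return A [ts_trace()].
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  chs <- unique(tab$channel)
  frames <- sort(unique(tab$frame))
  v <- sapply(chs, function(ch) tab$value[tab$channel == ch][order(tab$frame[tab$channel == ch])])
  v <- matrix(v, nrow = length(frames), dimnames = list(NULL, chs))
  times <- tab$time_s[match(frames, tab$frame)]
  ts_trace(v, frame_times = times, stimulus_frame = tab$stimulus_frame[1])
}
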