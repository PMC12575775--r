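# Readers and writers: PNG and MetaImage (.mhd/.raw) image/mask pairs,
# JSON dataset manifests, provenance records, nnU-Net-style export.
#
# Label convention on disk follows the CAMUS dialect {1 = LV, 2 = MYO,
# 3 = LA}; the LA label is remapped to background on load since this
# package deliberately does not model the atrium. NIfTI is not supported
# (no reader available in the target environment); use PNG or MetaImage.

DEFAULT_REMAP <- c("1" = 1L, "2" = 2L, "3" = 0L)

#' Read a labeled sample from an image/mask file pair
#'
#' Supported formats: 8/16-bit grayscale PNG and MetaImage (.mhd with a
#' local .raw). Images are rescaled to \[0, 1\]; mask values are remapped
#' through `remap` (default: LA -> background). Pixel spacing is taken
#' from the MetaImage header when present; a conflicting manifest spacing
#' is overridden with a warning (header wins).
#'
#' @param image_path,mask_path file paths.
#' @param record optional manifest record (list) with `spacing` and
#'   optional `geometry`.
#' @param remap named integer vector mapping raw mask values to labels.
#' @return a [labeled_sample()].
#' @export
read_sample <- function(image_path, mask_path, record = NULL,
                        remap = DEFAULT_REMAP) {
  img <- read_gray(image_path)
  mski <- read_gray(mask_path, as_labels = TRUE)
  msk <- mski$data
  bad <- setdiff(unique(as.integer(msk)), c(0L, as.integer(names(remap))))
  if (length(bad))
    abort_invalid(sprintf("mask contains unknown label(s): %s",
                          paste(bad, collapse = ", ")),
                  class = "echosynth_load_error")
  out <- matrix(0L, nrow(msk), ncol(msk))
  for (nm in names(remap)) out[msk == as.integer(nm)] <- remap[[nm]]
  if (!identical(dim(img$data), dim(out)))
    abort_invalid("image and mask shapes differ", class = "echosynth_load_error")
  spacing <- img$spacing
  if (!is.null(record$spacing)) {
    if (!is.null(spacing) && any(abs(spacing - as.numeric(record$spacing)) > 1e-9))
      warning("header spacing differs from manifest; header wins")
    if (is.null(spacing)) spacing <- as.numeric(record$spacing)
  }
  if (is.null(spacing)) spacing <- c(1, 1)
  geometry <- if (!is.null(record$geometry))
    sector_geometry(as.numeric(record$geometry$apex),
                    record$geometry$opening_angle,
                    record$geometry$radius,
                    record$geometry$axis_deg %||% 0)
  labeled_sample(img$data, out, geometry, spacing)
}

read_gray <- function(path, as_labels = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    if (as_labels) {
      a <- round(a * 255)
      storage.mode(a) <- "integer"
    }
    list(data = a, spacing = NULL)
  } else if (ext == "mhd") {
    read_mhd(path, as_labels)
  } else if (ext %in% c("nii", "gz")) {
    abort_invalid("NIfTI is not supported; use PNG or MetaImage",
                  class = "echosynth_load_error")
  } else {
    abort_invalid(sprintf("unknown image format: .%s", ext),
                  class = "echosynth_load_error")
  }
}

# ---- MetaImage ---------------------------------------------------------

read_mhd <- function(path, as_labels = FALSE) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2)
      kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])   # x (cols), y (rows)
  type <- kv$ElementType
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  n <- prod(dims)
  data <- switch(type,
    MET_UCHAR = as.numeric(readBin(raw_path, "integer", n, size = 1, signed = FALSE)),
    MET_USHORT = as.numeric(readBin(raw_path, "integer", n, size = 2, signed = FALSE,
                                    endian = "little")),
    MET_FLOAT = readBin(raw_path, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(raw_path, "double", n, size = 8, endian = "little"),
    abort_invalid(sprintf("unsupported ElementType %s", type),
                  class = "echosynth_load_error"))
  m <- t(matrix(data, dims[1], dims[2]))                 # x fastest -> transpose
  if (as_labels) {
    m <- round(m); storage.mode(m) <- "integer"
  } else if (type %in% c("MET_UCHAR", "MET_USHORT")) {
    m <- m / (2^(if (type == "MET_UCHAR") 8 else 16) - 1)
  }
  spacing <- if (!is.null(kv$ElementSpacing)) {
    sp <- as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
    c(sp[2], sp[1])                                      # (row, col) = (y, x)
  }
  list(data = m, spacing = spacing)
}

write_mhd <- function(data, path, spacing = NULL, type = "MET_FLOAT") {
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 2", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d", ncol(data), nrow(data)),
           sprintf("ElementType = %s", type),
           if (!is.null(spacing))
             sprintf("ElementSpacing = %.9g %.9g", spacing[2], spacing[1]),
           sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  v <- as.vector(t(data))
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (type == "MET_UCHAR") writeBin(as.integer(v), con, size = 1)
  else if (type == "MET_USHORT") writeBin(as.integer(v), con, size = 2, endian = "little")
  else writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

# ---- dataset writing ---------------------------------------------------

geometry_record <- function(g) {
  if (is.null(g)) NULL
  else list(apex = g$apex, opening_angle = g$opening_angle,
            radius = g$radius, axis_deg = g$axis_deg)
}

#' Write a dataset of labeled samples
#'
#' `layout = "native"` writes `<id>_image.png` / `<id>_mask.png` pairs, a
#' `manifest.json` with spacing and geometry per sample, and a
#' `provenance.json` recording each sample's transform history.
#' `layout = "nnunet"` writes `imagesTr/<CASE>_0000.png`,
#' `labelsTr/<CASE>.png` and a `dataset.json` description, the folder
#' convention expected by the nnU-Net trainer.
#'
#' @param samples list of [labeled_sample()].
#' @param out_dir output directory (created if missing).
#' @param layout "native" or "nnunet".
#' @param format "png" (8-bit; masks store raw label values) or "mhd"
#'   (lossless float image).
#' @param force overwrite an existing manifest.
#' @param records optional list of extra manifest fields per sample
#'   (view, cycle, frame_role, patient).
#' @return the manifest (or dataset.json) path, invisibly.
#' @export
write_augmented_dataset <- function(samples, out_dir,
                                    layout = c("native", "nnunet"),
                                    format = c("png", "mhd"),
                                    force = FALSE, records = NULL) {
  layout <- match.arg(layout); format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir,
                             if (layout == "native") "manifest.json" else "dataset.json")
  if (file.exists(manifest_path) && !force)
    abort_invalid(sprintf("%s exists; use force = TRUE", manifest_path),
                  class = "echosynth_collision_error")
  ids <- sprintf("sample_%04d", seq_along(samples))
  write_img <- function(img, path) {
    if (format == "png") png::writePNG(clamp(img, 0, 1), path)
    else write_mhd(img, path)
  }
  write_msk <- function(msk, path) {
    if (format == "png") png::writePNG(msk / 255, path)
    else write_mhd(msk, path, type = "MET_UCHAR")
  }
  ext <- if (format == "png") "png" else "mhd"
  if (layout == "native") {
    recs <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      ip <- file.path(out_dir, sprintf("%s_image.%s", ids[i], ext))
      mp <- file.path(out_dir, sprintf("%s_mask.%s", ids[i], ext))
      write_img(s$image, ip); write_msk(s$mask, mp)
      recs[[i]] <- c(list(id = ids[i], image = basename(ip), mask = basename(mp),
                          spacing = s$spacing,
                          geometry = geometry_record(s$geometry)),
                     if (!is.null(records)) records[[i]])
    }
    jsonlite::write_json(recs, manifest_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    prov <- lapply(seq_along(samples), function(i)
      list(id = ids[i], provenance = samples[[i]]$provenance))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    dir.create(file.path(out_dir, "imagesTr"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "labelsTr"), showWarnings = FALSE)
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      write_img(s$image, file.path(out_dir, "imagesTr",
                                   sprintf("%s_0000.%s", ids[i], ext)))
      write_msk(s$mask, file.path(out_dir, "labelsTr",
                                  sprintf("%s.%s", ids[i], ext)))
    }
    jsonlite::write_json(
      list(name = "echosynth export",
           labels = list(background = 0L, LV = 1L, MYO = 2L),
           numTraining = length(samples),
           file_ending = paste0(".", ext)),
      manifest_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest_path)
}

#' Read a dataset written by [write_augmented_dataset()]
#'
#' @param manifest_path path to a native-layout `manifest.json`.
#' @return list of [labeled_sample()] (manifest record in attribute
#'   `record`).
#' @export
read_dataset <- function(manifest_path) {
  recs <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  lapply(recs, function(r) {
    s <- read_sample(file.path(base, r$image), file.path(base, r$mask), r)
    attr(s, "record") <- r
    s
  })
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param size integer length-2 target (rows, cols).
#' @param method "bilinear" (images) or "nearest" (masks).
#' @return resized matrix.
#' @export
resize_image <- function(img, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  sr <- H / size[1]; sc <- W / size[2]
  g <- out_grid(size[1], size[2])
  src_r <- (g$r - 0.5) * sr + 0.5
  src_c <- (g$c - 0.5) * sc + 0.5
  if (method == "bilinear") warp_bilinear(img, src_r, src_c)
  else warp_nearest(img, src_r, src_c)
}
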