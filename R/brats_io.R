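# Reading BraTS-layout NIfTI cases and the preprocessing pipeline:
# center crop, axial 2D slice extraction, label remapping and per-modality
# intensity normalization.

BRATS_LABELS <- c(0, 1, 2, 4)

#' Remap BraTS labels \{0,1,2,4\} to contiguous classes \{0,1,2,3\}
#'
#' The remap is `0 -> 0, 1 -> 1, 2 -> 2, 4 -> 3` and [unmap_labels()] is its
#' inverse on these values.
#'
#' @param x integer array of BraTS label values.
#' @export
remap_labels <- function(x) {
  bad <- setdiff(unique(as.vector(x)), BRATS_LABELS)
  if (length(bad)) stop("non-BraTS label values: ", paste(bad, collapse = ", "))
  out <- x
  out[x == 4] <- 3L
  storage.mode(out) <- "integer"
  out
}

#' @rdname remap_labels
#' @export
unmap_labels <- function(x) {
  bad <- setdiff(unique(as.vector(x)), 0:3)
  if (length(bad)) stop("non-class label values: ", paste(bad, collapse = ", "))
  out <- x
  out[x == 3] <- 4L
  storage.mode(out) <- "integer"
  out
}

as_vol3d <- function(a) {
  a <- unclass(a)
  d <- dim(a)
  if (is.null(d) || length(d) < 2 || length(d) > 3) stop("expected a 2-d or 3-d volume")
  if (length(d) == 2) dim(a) <- c(d, 1L)
  array(as.numeric(a), dim(a))
}

#' Load one BraTS-layout case directory
#'
#' The directory must contain five NIfTI files whose names end in
#' `_t1`, `_t1ce`, `_t2`, `_flair` and `_seg` (with `.nii` or `.nii.gz`
#' extension).  All five volumes must share their shape and the
#' segmentation may contain only the BraTS label values \{0, 1, 2, 4\}.
#'
#' @param case_directory path to the case directory.
#' @return an `mm_case`: list with `images` (named list of 3-d arrays),
#'   `labels` (3-d integer array, BraTS values) and `id`.
#' @export
load_case <- function(case_directory) {
  if (!dir.exists(case_directory)) stop("no such case directory: ", case_directory)
  find1 <- function(tag) {
    fs <- list.files(case_directory,
                     pattern = paste0("_", tag, "\\.nii(\\.gz)?$"),
                     full.names = TRUE)
    if (tag == "t1") fs <- fs[!grepl("_t1ce\\.nii(\\.gz)?$", fs)]
    if (length(fs) != 1)
      stop("case ", basename(case_directory), ": expected exactly one '",
           tag, "' file, found ", length(fs))
    fs
  }
  images <- lapply(MODALITIES, function(mod) as_vol3d(RNifti::readNifti(find1(mod))))
  names(images) <- MODALITIES
  labels <- as_vol3d(RNifti::readNifti(find1("seg")))
  dims <- unique(lapply(c(images, list(labels)), dim))
  if (length(dims) != 1) stop("modality/label volume shapes differ")
  bad <- setdiff(unique(as.vector(labels)), BRATS_LABELS)
  if (length(bad)) stop("non-BraTS label values in seg: ", paste(bad, collapse = ", "))
  storage.mode(labels) <- "integer"
  structure(list(images = images, labels = labels, id = basename(case_directory)),
            class = "mm_case")
}

#' Center-crop a case to the working volume size
#'
#' @param vol an `mm_case`.
#' @param target target dimensions (height, width, depth), default
#'   `c(160, 160, 128)`.
#' @return the cropped `mm_case`; labels are cropped identically.
#' @export
crop_volume <- function(vol, target = c(160, 160, 128)) {
  d <- dim(vol$labels)
  if (any(d < target))
    stop("source volume ", paste(d, collapse = "x"),
         " smaller than crop target ", paste(target, collapse = "x"))
  start <- floor((d - target) / 2) + 1
  ix <- lapply(1:3, function(k) seq(start[k], length.out = target[k]))
  vol$images <- lapply(vol$images, function(a) a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  vol$labels <- vol$labels[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  vol
}

#' Per-modality intensity normalization
#'
#' The default z-scores each modality over its nonzero (brain) pixels and
#' leaves the zero background untouched; a constant nonzero foreground is
#' guarded with unit standard deviation.  `method = "none"` returns the
#' input unchanged.
#'
#' @param images named list (or array-valued list) of modality images.
#' @param method `"zscore_nonzero"` or `"none"`.
#' @export
normalize <- function(images, method = c("zscore_nonzero", "none")) {
  method <- match.arg(method)
  if (method == "none") return(images)
  lapply(images, function(img) {
    nz <- img != 0
    if (!any(nz)) return(img)
    mu <- mean(img[nz])
    sd <- stats::sd(img[nz])
    if (!is.finite(sd) || sd == 0) sd <- 1
    img[nz] <- (img[nz] - mu) / sd
    img
  })
}

#' Extract axial 2D slices as network inputs
#'
#' @param vol a (cropped) `mm_case`.
#' @param policy `"tumor_bearing"` keeps only slices whose label plane
#'   contains tumor; `"all"` keeps every slice.
#' @param normalize_method passed to [normalize()] per slice.
#' @return list of slice pairs: `images` (H, W, 4 array; T1, T1c, T2,
#'   FLAIR), `labels` (integer matrix, values 0:3), `case`, `slice`
#'   (0-based index into the cropped volume).
#' @export
extract_slices <- function(vol, policy = c("tumor_bearing", "all"),
                           normalize_method = "zscore_nonzero") {
  policy <- match.arg(policy)
  d <- dim(vol$labels)
  out <- list()
  for (k in seq_len(d[3])) {
    lab <- remap_labels(vol$labels[, , k])
    if (policy == "tumor_bearing" && !any(lab > 0)) next
    planes <- lapply(vol$images, function(a) a[, , k])
    planes <- normalize(planes, method = if (normalize_method == "none") "none" else normalize_method)
    img <- array(0, c(d[1], d[2], length(MODALITIES)))
    for (m in seq_along(MODALITIES)) img[, , m] <- planes[[MODALITIES[m]]]
    out[[length(out) + 1L]] <- list(images = img, labels = lab,
                                    case = vol$id, slice = k - 1L)
  }
  out
}

#' Turn a phantom case into a slice pair without touching disk
#'
#' @param case an `mm_phantom_case`.
#' @param normalize_method passed to [normalize()].
#' @export
phantom_slice <- function(case, normalize_method = "zscore_nonzero") {
  planes <- normalize(case$images, method = normalize_method)
  d <- dim(case$labels)
  img <- array(0, c(d[1], d[2], length(MODALITIES)))
  for (m in seq_along(MODALITIES)) img[, , m] <- planes[[MODALITIES[m]]]
  list(images = img, labels = case$labels, case = "phantom", slice = 0L)
}
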