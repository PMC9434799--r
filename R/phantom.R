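# Synthetic multimodal brain-tumor phantom.
#
# Each case is a set of four co-registered single-channel images (T1, T1c,
# T2, FLAIR) over a skull-stripped "brain" ellipse, with three nested
# elliptical tumor regions: enhancing tumor innermost, necrotic core
# filling the TC shell and edema filling the WT shell.  Per-tissue mean
# intensities follow a contrast table and pixels get additive Gaussian
# noise; outside the brain everything is exactly zero, as in skull-stripped
# BraTS data.

MODALITIES <- c("t1", "t1ce", "t2", "flair")

#' Default phantom contrast table
#'
#' Mean intensity per (modality, tissue class).  The defaults make each
#' region most conspicuous in a different modality: enhancing tumor lights
#' up in T1c, edema (hence the whole tumor) in FLAIR/T2, while T1 shows
#' little tumor contrast — mirroring why the four modalities are acquired.
#'
#' @return numeric matrix, rows = modalities (t1, t1ce, t2, flair),
#'   columns = tissue classes (background, necrosis, edema, enhancing).
#' @export
default_contrast <- function() {
  m <- rbind(
    t1    = c(background = 80, necrosis = 45, edema = 65, enhancing = 75),
    t1ce  = c(background = 80, necrosis = 50, edema = 70, enhancing = 200),
    t2    = c(background = 70, necrosis = 140, edema = 160, enhancing = 110),
    flair = c(background = 70, necrosis = 100, edema = 180, enhancing = 120))
  m
}

#' Phantom case specification
#'
#' @param image_size square image size in pixels; must be divisible by 16
#'   (the network's total downsampling factor).
#' @param tumor_center tumor center (row, col) in pixels; default image
#'   center.
#' @param region_radii strictly decreasing positive radii (WT, TC, ET) in
#'   pixels, each `< image_size / 2`.
#' @param contrast_table matrix as in [default_contrast()].
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed nonnegative integer seed; the case is fully reproducible.
#' @param empty_et if `TRUE` the enhancing region is absent and the whole
#'   tumor core is necrotic (exercises the ET special-case scoring rule).
#' @param axis_ratio ellipse axis ratio (row semi-axis = r * ratio, col
#'   semi-axis = r / ratio).
#' @export
phantom_spec <- function(image_size = 160L, tumor_center = NULL,
                         region_radii = c(wt = 30, tc = 18, et = 8),
                         contrast_table = default_contrast(), noise_sd = 5,
                         seed = 0L, empty_et = FALSE, axis_ratio = 1.1) {
  if (is.null(tumor_center)) tumor_center <- c(image_size / 2, image_size / 2)
  spec <- list(image_size = as.integer(image_size), tumor_center = tumor_center,
               region_radii = unname(region_radii), contrast_table = contrast_table,
               noise_sd = noise_sd, seed = as.integer(seed),
               empty_et = isTRUE(empty_et), axis_ratio = axis_ratio)
  validate_phantom_spec(spec)
  structure(spec, class = "mm_phantom_spec")
}

validate_phantom_spec <- function(spec) {
  r <- spec$region_radii
  if (length(r) != 3) stop("region_radii must have length 3 (WT, TC, ET)")
  r_eff <- if (spec$empty_et) r[1:2] else r
  if (any(diff(r_eff) >= 0) || any(r_eff <= 0))
    stop("region_radii must be strictly decreasing positive values (WT > TC > ET)")
  if (any(r >= spec$image_size / 2))
    stop("region radii must be smaller than half the image size")
  if (spec$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (spec$image_size %% 16 != 0) stop("image_size must be divisible by 16")
  if (spec$seed < 0) stop("seed must be nonnegative")
  invisible(spec)
}

ellipse_mask <- function(size, center, r, ratio) {
  if (r <= 0) return(matrix(FALSE, size, size))
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - center[1]) / (r * ratio))^2 + ((cols - center[2]) / (r / ratio))^2 <= 1
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()].
#' @return an `mm_phantom_case`: list with `images` (named list of
#'   image_size x image_size matrices, modalities t1/t1ce/t2/flair),
#'   `labels` (integer matrix, values 0:3) and `spec`.
#' @export
generate_case <- function(spec) {
  validate_phantom_spec(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  sz <- spec$image_size
  ctr <- spec$tumor_center
  brain <- ellipse_mask(sz, c(sz / 2, sz / 2), 0.42 * sz, 1.1)
  wt <- ellipse_mask(sz, ctr, spec$region_radii[1], spec$axis_ratio) & brain
  tc <- ellipse_mask(sz, ctr, spec$region_radii[2], spec$axis_ratio) & brain
  et <- if (spec$empty_et) matrix(FALSE, sz, sz) else
    ellipse_mask(sz, ctr, spec$region_radii[3], spec$axis_ratio) & brain
  labels <- matrix(0L, sz, sz)
  labels[wt] <- 2L                        # edema shell
  labels[tc] <- 1L                        # necrotic core shell
  labels[et] <- 3L                        # enhancing tumor
  tissue <- matrix(1L, sz, sz)            # 1 = (brain) background column index
  tissue[labels == 1L] <- 2L
  tissue[labels == 2L] <- 3L
  tissue[labels == 3L] <- 4L
  images <- lapply(MODALITIES, function(mod) {
    img <- matrix(spec$contrast_table[mod, ][tissue], sz, sz)
    img <- img + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
    img[!brain] <- 0
    img
  })
  names(images) <- MODALITIES
  structure(list(images = images, labels = labels, spec = spec),
            class = "mm_phantom_case")
}

#' Generate a jittered phantom dataset
#'
#' Case-level jitter perturbs the tumor center, the region radii and the
#' contrast table from a stream seeded by `base_spec$seed`; radii that come
#' out non-nested are resampled.  A fixed fraction of cases (rounded) is
#' generated with an empty enhancing region; their positions within the
#' dataset are drawn from the same seeded stream.
#'
#' @param n_cases number of cases.
#' @param base_spec the [phantom_spec()] to perturb.
#' @param jitter list with `center` (max absolute shift, px), `radii_frac`
#'   and `contrast_frac` (relative perturbation half-widths).
#' @param empty_et_fraction fraction of cases with no enhancing tumor.
#' @return list of `mm_phantom_case` named `case_001`, ...
#' @export
generate_dataset <- function(n_cases, base_spec,
                             jitter = list(center = 6, radii_frac = 0.15,
                                           contrast_frac = 0.08),
                             empty_et_fraction = 0.25) {
  stopifnot(n_cases >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(base_spec$seed)
  n_empty <- round(n_cases * empty_et_fraction)
  empty_idx <- if (n_empty > 0) sample(n_cases, n_empty) else integer(0)
  specs <- lapply(seq_len(n_cases), function(i) {
    for (attempt in 1:100) {
      ctr <- base_spec$tumor_center + stats::runif(2, -jitter$center, jitter$center)
      rr <- base_spec$region_radii *
        (1 + stats::runif(3, -jitter$radii_frac, jitter$radii_frac))
      ct <- base_spec$contrast_table *
        (1 + matrix(stats::runif(length(base_spec$contrast_table),
                                 -jitter$contrast_frac, jitter$contrast_frac),
                    nrow(base_spec$contrast_table)))
      empty <- i %in% empty_idx
      ok <- all(diff(if (empty) rr[1:2] else rr) < 0) && all(rr < base_spec$image_size / 2)
      if (ok) {
        return(phantom_spec(base_spec$image_size, ctr, rr, ct,
                            base_spec$noise_sd,
                            seed = (base_spec$seed + i * 7919L) %% 2147483647L,
                            empty_et = empty, axis_ratio = base_spec$axis_ratio))
      }
    }
    stop("could not draw nested radii after 100 attempts")
  })
  cases <- lapply(specs, generate_case)
  names(cases) <- sprintf("case_%03d", seq_len(n_cases))
  cases
}

#' Write phantom cases as a BraTS-style directory tree
#'
#' One subdirectory per case holding five NIfTI files
#' (`<id>_t1.nii.gz`, `_t1ce`, `_t2`, `_flair`, `_seg`); the segmentation
#' uses the BraTS label values \{0, 1, 2, 4\}.  A `manifest.txt` index is
#' written at the top level.
#'
#' @param cases list of `mm_phantom_case` (named by case id).
#' @param directory output directory, created if needed.
#' @param force overwrite an existing nonempty directory.
#' @export
write_brats_layout <- function(cases, directory, force = FALSE) {
  stopifnot(length(cases) >= 1)
  if (dir.exists(directory) && length(list.files(directory)) && !force)
    stop("directory ", directory, " is not empty; use force = TRUE")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ids <- names(cases)
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_along(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cdir <- file.path(directory, ids[i])
    dir.create(cdir, showWarnings = FALSE)
    for (mod in MODALITIES) {
      img <- cs$images[[mod]]
      RNifti::writeNifti(array(img, c(dim(img), 1L)),
                         file.path(cdir, paste0(ids[i], "_", mod, ".nii.gz")))
    }
    seg <- unmap_labels(cs$labels)
    RNifti::writeNifti(array(as.numeric(seg), c(dim(seg), 1L)),
                       file.path(cdir, paste0(ids[i], "_seg.nii.gz")))
  }
  writeLines(ids, file.path(directory, "manifest.txt"))
  invisible(directory)
}
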