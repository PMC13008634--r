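## Image input/output: 8/16-bit grayscale PNG and TIFF mapped linearly to
## [0, 1], plus axial slice extraction from NIfTI volumes with per-slice
## min-max normalization.

#' Read a grayscale image into \[0, 1\]
#'
#' PNG and TIFF are read through the `png`/`tiff` packages (which already
#' return linearly scaled doubles); RGB input is averaged to one channel.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric matrix with values in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("read_image: unsupported extension: ", ext))
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3L])),
                                         drop = FALSE], c(1L, 2L), mean)
  pmin(pmax(a, 0), 1)
}

#' Write a grayscale image from \[0, 1\]
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path; extension selects PNG or TIFF.
#' @param bits 8 or 16 bit depth; PNG output is always 8-bit (the writer's
#'   limit), TIFF honours the request — use TIFF where 16-bit precision
#'   matters.
#' @return invisibly, `path`.
#' @export
write_image <- function(img, path, bits = 16L) {
  stopifnot(is.matrix(img), bits %in% c(8L, 16L))
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
         stop("write_image: unsupported extension: ", ext))
  invisible(path)
}

#' Extract axial slices from a NIfTI volume
#'
#' Each requested slice is min-max normalized to \[0, 1\] independently
#' (constant slices map to 0).
#'
#' @param path .nii or .nii.gz file.
#' @param indices integer slice indices along the third axis; default all.
#' @return list of numeric matrices.
#' @export
read_nifti_slices <- function(path, indices = NULL) {
  vol <- RNifti::readNifti(path)
  a <- as.array(vol)
  if (length(dim(a)) < 3L) stop("read_nifti_slices: expected a 3D volume")
  nz <- dim(a)[3L]
  if (is.null(indices)) indices <- seq_len(nz)
  stopifnot(all(indices >= 1L & indices <= nz))
  lapply(indices, function(i) {
    sl <- a[, , i]
    rng <- range(sl)
    if (rng[2] > rng[1]) (sl - rng[1]) / (rng[2] - rng[1]) else sl * 0
  })
}

#' Generate a phantom dataset on disk with a manifest
#'
#' Writes `hr/`, `lr/` and `ref/` PNG images plus `manifest.csv` with columns
#' `sample_id, hr_path, lr_path, ref_path, scale, seed`. References are drawn
#' from the same phantom corpus (a different seed than the target).
#'
#' @param n_slices number of HR slices.
#' @param size HR side length in pixels.
#' @param scale upscaling factor in `{2, 3, 4}`.
#' @param seed base RNG seed; slice `i` uses `seed + i`.
#' @param out_dir output directory (created if missing).
#' @param params_fn optional function(seed) returning [phantom_params()];
#'   defaults to the standard phantom at the requested size.
#' @return the manifest as a data.frame, invisibly written to CSV.
#' @export
generate_dataset <- function(n_slices, size, scale, seed, out_dir,
                             params_fn = NULL) {
  stopifnot(n_slices >= 2L, scale %in% c(2L, 3L, 4L))
  if (is.null(params_fn))
    params_fn <- function(s) phantom_params(size = size, seed = s)
  for (d in c("hr", "lr", "ref")) dir.create(file.path(out_dir, d),
                                             recursive = TRUE,
                                             showWarnings = FALSE)
  ref_of <- with_seed_local(seed, vapply(seq_len(n_slices), function(i) {
    sample(setdiff(seq_len(n_slices), i), 1L)
  }, integer(1)))
  rows <- vector("list", n_slices)
  hr_imgs <- lapply(seq_len(n_slices),
                    function(i) crop_to_multiple(
                      generate_phantom(params_fn(seed + i)), scale))
  for (i in seq_len(n_slices)) {
    hr <- hr_imgs[[i]]
    lr <- bicubic_resize(hr, nrow(hr) %/% scale, ncol(hr) %/% scale)
    id <- sprintf("s%04d", i)
    paths <- c(hr = file.path(out_dir, "hr", paste0(id, ".png")),
               lr = file.path(out_dir, "lr", paste0(id, ".png")),
               ref = file.path(out_dir, "ref", paste0(id, ".png")))
    write_image(hr, paths[["hr"]])
    write_image(lr, paths[["lr"]])
    write_image(hr_imgs[[ref_of[i]]], paths[["ref"]])
    rows[[i]] <- data.frame(sample_id = id, hr_path = paths[["hr"]],
                            lr_path = paths[["lr"]], ref_path = paths[["ref"]],
                            scale = scale, seed = seed + i,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
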