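# NIfTI interchange and run manifests. Convention, used everywhere:
# 0-based case indices, (row, col) array ordering, spacing in mm.

#' Write a stack of image slices to NIfTI
#'
#' @param slices list of [ImageSlice-class] with identical shapes/spacing
#'   (a single slice is accepted).
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(slices, path) {
  if (is(slices, "ImageSlice")) slices <- list(slices)
  d <- dim(slices[[1]]@values)
  arr <- array(0, c(d, length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]@values
  sp <- slices[[1]]@spacing
  img <- RNifti::asNifti(arr, pixdim = c(sp[1], sp[2], 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as image slices
#'
#' Applies the NIfTI scaling slope/intercept (handled by the reader) and
#' carries the pixel spacing through.
#'
#' @param path NIfTI file.
#' @param modality modality tag for the returned slices.
#' @return list of [ImageSlice-class] (one per slice).
#' @export
readVolume <- function(path, modality = "CT") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pd <- RNifti::pixdim(img)
  sp <- pd[1:2]
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  lapply(seq_len(dim(arr)[3]), function(i)
    ImageSlice(.clipHU(arr[, , i]), spacing = sp, modality = modality))
}

#' Write a dose grid to NIfTI
#' @param dose a [DoseGrid-class].
#' @param path output path.
#' @export
writeDose <- function(dose, path) {
  img <- RNifti::asNifti(array(dose@values, c(dim(dose@values), 1)),
                         pixdim = c(dose@spacing, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dose grid from NIfTI
#' @param path NIfTI file.
#' @param role `"reference"` or `"evaluated"`.
#' @export
readDose <- function(path, role = "reference") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  DoseGrid(pmax(arr, 0), spacing = RNifti::pixdim(img)[1:2], role = role)
}

#' Write a phantom dataset to disk
#'
#' One NIfTI per case and member (cbct/dct) plus a JSON manifest recording
#' case ids, split membership and the root seed.
#'
#' @param dataset result of [generatePhantomDataset()].
#' @param dir output directory (created).
#' @param force overwrite an existing manifest.
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir, force = FALSE) {
  manifestPath <- file.path(dir, "manifest.json")
  if (file.exists(manifestPath) && !force)
    stop("dataset already exists at ", dir, " (use force = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in dataset$samples) {
    writeVolume(s@cbct, file.path(dir, paste0(s@caseId, "_cbct.nii.gz")))
    writeVolume(s@dct, file.path(dir, paste0(s@caseId, "_dct.nii.gz")))
  }
  jsonlite::write_json(dataset$manifest, manifestPath, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(manifestPath)
}

#' Read a phantom dataset written by [writeDataset()]
#' @param dir dataset directory containing `manifest.json`.
#' @return list with `samples` and `manifest`, as from
#'   [generatePhantomDataset()].
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  samples <- lapply(manifest$caseId, function(id) {
    cbct <- readVolume(file.path(dir, paste0(id, "_cbct.nii.gz")), "CBCT")[[1]]
    dct <- readVolume(file.path(dir, paste0(id, "_dct.nii.gz")), "CT")[[1]]
    PairedSample(cbct = cbct, dct = dct, caseId = id)
  })
  list(samples = samples, manifest = manifest)
}

#' Save / load a trained network
#'
#' Checkpoints store the parameter tree together with its
#' [NetworkConfig-class] and training provenance, so `synthesize` can be
#' run later from the command line.
#'
#' @param net a `sctNetwork`.
#' @param path checkpoint file (`.rds`).
#' @export
saveNetwork <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "sctNetwork")) stop("not a network checkpoint: ", path)
  net
}
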