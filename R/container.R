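#' Write / read an epoched-EEG dataset container
#'
#' One directory per dataset: per participant a little-endian row-major
#' (trials, channels, samples; samples fastest) double-precision binary
#' payload plus a JSON sidecar (sampling rate, times, channel names, trial
#' table, identity), and a dataset manifest listing every participant file
#' with shapes and checksums. The round trip is bit exact.
#'
#' @param dataset list of [epoch_set()] objects.
#' @param path directory to create/write.
#' @return `write_container` returns `path` invisibly; `read_container`
#'   returns the list of `EpochSet` in manifest order.
#' @export
write_container <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (ep in dataset) {
    id <- ep$participant_id
    datafile <- paste0(id, ".dat")
    vec <- as.vector(aperm(ep$data, c(3, 2, 1))) # samples, channels, trials
    con <- file(file.path(path, datafile), "wb")
    writeBin(vec, con, size = 8, endian = "little")
    close(con)
    sidecar <- list(
      participant_id = id, group_label = ep$group_label,
      sfreq = ep$sfreq, times = ep$times, channel_names = ep$channel_names,
      shape = dim(ep$data), byte_order = "little", dtype = "float64",
      trials = data.frame(condition = as.character(ep$trial_labels),
                          correctness = ep$correctness, rt = ep$rt))
    jsonlite::write_json(sidecar, file.path(path, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    entries[[length(entries) + 1L]] <- list(
      participant_id = id, data = datafile, sidecar = paste0(id, ".json"),
      shape = dim(ep$data), checksum = format(sum(vec), digits = 17))
  }
  jsonlite::write_json(list(format = "erpdecode-epochs-v1",
                            n_participants = length(dataset),
                            participants = entries),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  lapply(manifest$participants, function(entry) {
    sc <- jsonlite::read_json(file.path(path, entry$sidecar),
                              simplifyVector = TRUE)
    shape <- as.integer(unlist(entry$shape))
    n <- prod(shape)
    fpath <- file.path(path, entry$data)
    if (!file.exists(fpath)) stop("missing data file ", entry$data)
    if (file.info(fpath)$size != 8 * n)
      stop("shape mismatch: sidecar declares ", paste(shape, collapse = "x"),
           " but payload holds ", file.info(fpath)$size / 8, " doubles")
    con <- file(fpath, "rb")
    vec <- readBin(con, "double", n = n, size = 8, endian = "little")
    close(con)
    if (!is.null(entry$checksum) &&
        format(sum(vec), digits = 17) != entry$checksum)
      stop("checksum failure for ", entry$data)
    data <- aperm(array(vec, rev(shape)), c(3, 2, 1))
    epoch_set(data, sc$sfreq, sc$times, sc$trials$condition,
              sc$trials$correctness, sc$trials$rt,
              sc$participant_id, sc$group_label, sc$channel_names)
  })
}
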