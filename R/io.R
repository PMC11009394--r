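# TIFF and tabular input/output.
#
# Scenes travel as (multi-page) TIFF. Pixel-size metadata is resolved in
# this order: TIFF resolution tags (x.resolution + resolution.unit; the
# ImageJ convention of unit "none" meaning pixels per micrometre is
# honoured), then a JSON sidecar written next to the file by
# writeImageScene(), then the explicit override argument. With none of the
# three, reading errors: every downstream quantity is in physical units.

pixelSizeFromInfo <- function(info) {
    xres <- attr(info, "x.resolution")
    if (is.null(xres) || !is.finite(xres) || xres <= 0) return(NULL)
    unit <- attr(info, "resolution.unit")
    if (is.null(unit)) unit <- "inch" # TIFF default
    switch(unit,
        inch = 25400 / xres,
        cm = 10000 / xres,
        # ImageJ writes unit "none" with resolution in px/µm
        none = 1 / xres,
        NULL)
}

#' Read a TIFF file into an ImageScene
#'
#' Single- or multi-page TIFF. Multi-page files are interpreted as channels
#' of one frame by default, or as frames of a single-channel time lapse with
#' \code{timelapse = TRUE}; a sidecar written by [writeImageScene()]
#' resolves the layout automatically.
#'
#' @param path TIFF file
#' @param pixelSize override in µm/px, used when the file carries no pixel
#'   size in its resolution tags or sidecar
#' @param channels optional channel names
#' @param frameInterval minutes between frames (time lapse)
#' @param timelapse treat pages as frames rather than channels
#' @return an [ImageScene-class]
#' @export
readImageScene <- function(path, pixelSize = NULL, channels = NULL,
                           frameInterval = NA_real_, timelapse = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- tryCatch(
        tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
        error = function(e) stop("unreadable TIFF: ", path, " (",
                                 conditionMessage(e), ")"))
    if (!is.list(pages)) pages <- list(pages)
    ps <- pixelSizeFromInfo(pages[[1L]])
    pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L) p <- p[, , 1L] # collapse grey-alpha etc.
        # drop the TIFF info attributes, keep a clean numeric matrix
        matrix(as.numeric(p), nrow(p), ncol(p))
    })
    sidecar <- paste0(path, ".json")
    meta <- NULL
    if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (is.null(ps) && !is.null(meta$pixel_size_um))
            ps <- as.numeric(meta$pixel_size_um)
        if (is.null(channels) && !is.null(meta$channels))
            channels <- as.character(meta$channels)
        if (!is.finite(frameInterval) && !is.null(meta$frame_interval_min))
            frameInterval <- as.numeric(meta$frame_interval_min)
        if (!is.null(meta$layout) && identical(meta$layout, "frames"))
            timelapse <- TRUE
    }
    if (is.null(ps)) ps <- pixelSize
    if (is.null(ps)) stop("pixel size unknown: ", path,
                          " has no resolution metadata and no override given")
    if (timelapse && length(pages) > 1L) {
        arr <- array(0, c(dim(pages[[1L]]), length(pages)))
        for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
        pixels <- list(arr)
        if (is.null(channels)) channels <- "ch1"
    } else {
        pixels <- pages
        if (is.null(channels)) channels <- paste0("ch", seq_along(pages))
    }
    ImageScene(pixels, channels = channels, pixelSize = ps,
               frameInterval = frameInterval)
}

#' Write an ImageScene to a TIFF file (with metadata sidecar)
#'
#' Intensities are written as 16-bit samples, so integer intensities up to
#' 65535 round-trip bit-exactly. Multi-channel single-frame scenes write one
#' page per channel; single-channel time lapses one page per frame. A JSON
#' sidecar (\code{<path>.json}) records pixel size, channel names, frame
#' interval and page layout.
#'
#' @param scene an [ImageScene-class]
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @export
writeImageScene <- function(scene, path) {
    stopifnot(is(scene, "ImageScene"))
    nt <- nFrames(scene)
    if (nt > 1L && length(scene@channels) > 1L)
        stop("multi-channel time lapses are not supported by the writer; ",
             "write one file per channel")
    if (nt > 1L) {
        arr <- scene@pixels[[1L]]
        pages <- lapply(seq_len(nt), function(i) arr[, , i])
        layout <- "frames"
    } else {
        pages <- scene@pixels
        layout <- "channels"
    }
    mx <- max(vapply(pages, max, 0))
    if (mx > 65535) stop("intensities exceed the 16-bit writer range")
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta <- list(pixel_size_um = scene@pixelSize,
                 channels = scene@channels, layout = layout)
    if (is.finite(scene@frameInterval))
        meta$frame_interval_min <- scene@frameInterval
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Result tables with provenance
#'
#' A ResultTable is a data.frame whose \code{provenance} attribute records
#' where its rows came from (input path, parameters, package version, seed).
#' [writeResults()] serialises the provenance as \code{#}-prefixed header
#' lines above the CSV header so files remain self-describing yet
#' re-readable with any CSV reader.
#'
#' @param df data.frame of measurement records
#' @param provenance named list (input, parameters, seed, ...)
#' @return the data.frame with class \code{ResultTable}
#' @export
resultTable <- function(df, provenance = list()) {
    stopifnot(is.data.frame(df))
    if (anyDuplicated(names(df))) stop("column names must be unique")
    provenance$software <- paste0("podoquant ",
        as.character(utils::packageVersion("podoquant")))
    attr(df, "provenance") <- provenance
    class(df) <- c("ResultTable", class(df))
    df
}

#' @rdname resultTable
#' @param table a ResultTable (or plain data.frame)
#' @param path output CSV path
#' @param allowEmpty write a header-only file for an empty table
#' @export
writeResults <- function(table, path, allowEmpty = FALSE) {
    if (nrow(table) == 0L && !allowEmpty)
        stop("refusing to write an empty result table (set allowEmpty)")
    prov <- attr(table, "provenance")
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(prov) && length(prov)) {
        flat <- vapply(prov, function(v)
            paste(format(unlist(v), trim = TRUE), collapse = " "), "")
        writeLines(paste0("# ", names(prov), ": ", flat), con)
    }
    utils::write.csv(as.data.frame(table), con, row.names = FALSE)
    invisible(path)
}

#' @rdname resultTable
#' @export
readResults <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    prov <- list()
    if (any(hdr)) {
        kv <- sub("^# *", "", lines[hdr])
        keys <- sub(":.*$", "", kv)
        vals <- sub("^[^:]*: *", "", kv)
        prov <- as.list(vals)
        names(prov) <- keys
    }
    df <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"))
    attr(df, "provenance") <- prov
    class(df) <- c("ResultTable", class(df))
    df
}

#' Read a seed-point file for semi-automatic cell segmentation
#'
#' Delimited text with columns \code{scene, cell_id, row, col}
#' (1-based pixel coordinates).
#'
#' @param path CSV file
#' @return data.frame of seeds
#' @export
readSeeds <- function(path) {
    df <- utils::read.csv(path)
    need <- c("scene", "cell_id", "row", "col")
    if (!all(need %in% names(df)))
        stop("seed file must have columns: ", paste(need, collapse = ", "))
    df
}
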