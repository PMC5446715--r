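# Plain-text I/O: TSV/CSV matrices (probes as rows, first column the probe
# id, header row of sample ids), sample tables, and JSON run manifests.
# Floats are written at 17 significant digits so write -> read round-trips
# bit-exactly.

#' Read a methylation matrix from TSV/CSV
#'
#' Expects probes as rows, the probe identifier in the first column and a
#' header row of sample identifiers. The comma-vs-tab dialect is
#' auto-detected and recorded in attribute \code{"dialect"} of the returned
#' object's metadata.
#'
#' @param path file path.
#' @param scale \code{"M"} or \code{"beta"}; the scale invariants are
#'   enforced on read (beta strictly in (0,1), M finite).
#' @return A \linkS4class{MethylationSet}.
#' @export
readMethylationMatrix <- function(path, scale = c("M", "beta")) {
    scale <- match.arg(scale)
    if (!file.exists(path)) stop("no such file: ", path)
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2L) stop("expected a probe-id column plus sample columns")
    probeIds <- as.character(dt[[1L]])
    if (anyDuplicated(probeIds))
        stop("duplicate probe identifiers: ",
             paste(unique(probeIds[duplicated(probeIds)])[1:3], collapse = ", "))
    vals <- dt[, -1L, drop = FALSE]
    bad <- !vapply(vals, is.numeric, logical(1))
    if (any(bad))
        stop("non-numeric values in column(s): ",
             paste(names(vals)[bad], collapse = ", "))
    m <- as.matrix(vals)
    rownames(m) <- probeIds
    if (scale == "beta" && (any(m <= 0) || any(m >= 1))) {
        off <- which(m <= 0 | m >= 1, arr.ind = TRUE)[1L, ]
        stop(sprintf("beta-value out of (0,1) at probe '%s', sample '%s'",
                     probeIds[off[1L]], colnames(m)[off[2L]]))
    }
    if (anyNA(m) || any(!is.finite(m))) {
        off <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing/non-finite value at probe '%s', sample '%s'",
                     probeIds[off[1L]], colnames(m)[off[2L]]))
    }
    ms <- MethylationSet(m, scale = scale)
    S4Vectors::metadata(ms)$dialect <-
        if (grepl("\\.csv$", path, ignore.case = TRUE)) "comma" else "tab"
    ms
}

#' @rdname readMethylationMatrix
#' @param x a \linkS4class{MethylationSet}.
#' @param sep \code{"\t"} or \code{","}.
#' @export
writeMethylationMatrix <- function(x, path, sep = "\t") {
    stopifnot(is(x, "MethylationSet"))
    v <- SummarizedExperiment::assay(x, "meth")
    df <- data.frame(probe_id = rownames(v), .fmt17(v), check.names = FALSE)
    data.table::fwrite(df, path, sep = sep)
    invisible(path)
}

# 17 significant digits: enough for binary64 values to round-trip exactly
.fmt17 <- function(v) {
    out <- sprintf("%.17g", v)
    dim(out) <- dim(v)
    colnames(out) <- colnames(v)
    as.data.frame(out)
}

#' Write an SVA fit and its run manifest to disk
#'
#' Writes three plain-text files into \code{dir}: \code{sv.tsv} (samples x
#' K, header SV1..SVK plus a sample-id column), \code{weights.tsv} (probe
#' id, weight) and \code{manifest.json} (K, alpha, mode, iterations,
#' convergence record, threshold, seed, package version, timestamp).
#'
#' @param fit an \linkS4class{SVAFit}.
#' @param dir output directory (created if missing).
#' @param probeIds,sampleIds identifiers for the weight and SV tables.
#' @param seed the seed the run used (stored in the manifest; NA if none).
#' @param corrThreshold the convergence threshold used.
#' @return Invisibly, the manifest as a list.
#' @export
writeSVAResult <- function(fit, dir, probeIds = NULL, sampleIds = NULL,
                           seed = NA_integer_, corrThreshold = 0.999) {
    stopifnot(is(fit, "SVAFit"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sv <- fit@sv
    colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
    if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(nrow(sv)))
    if (is.null(probeIds)) probeIds <- sprintf("cg%06d", seq_along(fit@weights))
    data.table::fwrite(data.frame(sample_id = sampleIds, .fmt17(sv)),
                       file.path(dir, "sv.tsv"), sep = "\t")
    data.table::fwrite(data.frame(probe_id = probeIds,
                                  weight = sprintf("%.17g", fit@weights)),
                       file.path(dir, "weights.tsv"), sep = "\t")
    manifest <- list(K = fit@K, alpha = fit@alpha, mode = fit@mode,
                     iterations = fit@nIter, converged = fit@converged,
                     weight_correlation = fit@weightCorr,
                     corr_threshold = corrThreshold, seed = seed,
                     package = "iwsva",
                     version = as.character(packageVersion("iwsva")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        "%Y-%m-%dT%H:%M:%SZ"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
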