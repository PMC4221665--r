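## Plain-text I/O: catalogs, trait tables, Z matrices, GMT gene sets,
## genetic-interaction tables.

#' Construct a MorphoSet from a value matrix and culture metadata
#'
#' @param values numeric matrix, parameters x cultures, rownames are
#'   parameter ids present in \code{catalog}.
#' @param colData data.frame with one row per culture and columns
#'   \code{strain_id}, \code{group}, \code{replicate_index}.
#' @param catalog a \linkS4class{ParameterCatalog}.
#' @param trials optional matrix of per-culture trial counts (cells scored),
#'   same shape as \code{values}; required when binomial traits are present.
#' @return A \linkS4class{MorphoSet}.
#' @export
MorphoSet <- function(values, colData, catalog, trials = NULL) {
    values <- as.matrix(values)
    info <- paramInfo(catalog)
    unknown <- setdiff(rownames(values), info$param_id)
    if (length(unknown))
        stop("unknown parameter column(s): ", paste(unknown, collapse = ", "))
    rd <- info[match(rownames(values), info$param_id), , drop = FALSE]
    rownames(rd) <- rd$param_id
    if (is.null(trials)) {
        trials <- matrix(NA_real_, nrow(values), ncol(values),
                         dimnames = dimnames(values))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(value = values, trials = as.matrix(trials)),
        rowData = S4Vectors::DataFrame(rd),
        colData = S4Vectors::DataFrame(colData))
    methods::new("MorphoSet", se)
}

#' Read / write a parameter catalog as TSV
#'
#' The file has columns \code{param_id}, \code{family}, \code{link},
#' \code{mean_partner_id}, \code{description}.
#'
#' @param path file path.
#' @return \code{readParameterCatalog}: a \linkS4class{ParameterCatalog}.
#' @export
readParameterCatalog <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
    df$mean_partner_id[is.na(df$mean_partner_id)] <- ""
    ParameterCatalog(df)
}

#' @rdname readParameterCatalog
#' @param catalog a \linkS4class{ParameterCatalog} to write.
#' @export
writeParameterCatalog <- function(catalog, path) {
    utils::write.table(paramInfo(catalog), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write replicate-level trait tables as TSV
#'
#' The values file has one row per culture with columns \code{culture_id},
#' \code{strain_id}, \code{group}, \code{replicate_index} followed by one
#' column per parameter. Trial counts for binomial traits travel in a
#' companion TSV of the same layout.
#'
#' @param path values TSV path.
#' @param catalog a \linkS4class{ParameterCatalog}.
#' @param trialsPath optional companion TSV of trial counts.
#' @return \code{readTraitTable}: a \linkS4class{MorphoSet}.
#' @export
readTraitTable <- function(path, catalog, trialsPath = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    meta <- c("culture_id", "strain_id", "group", "replicate_index")
    vals <- t(as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE]))
    colnames(vals) <- df$culture_id
    trials <- NULL
    if (!is.null(trialsPath)) {
        tf <- utils::read.delim(trialsPath, stringsAsFactors = FALSE,
                                check.names = FALSE)
        tm <- t(as.matrix(tf[, setdiff(colnames(tf), meta), drop = FALSE]))
        trials <- matrix(NA_real_, nrow(vals), ncol(vals),
                         dimnames = dimnames(vals))
        trials[rownames(tm), ] <- tm
    }
    cd <- df[, intersect(meta, colnames(df)), drop = FALSE]
    rownames(cd) <- df$culture_id
    MorphoSet(vals, cd, catalog, trials)
}

#' @rdname readTraitTable
#' @param mset a \linkS4class{MorphoSet} to write.
#' @export
writeTraitTable <- function(mset, path, trialsPath = NULL) {
    cd <- as.data.frame(SummarizedExperiment::colData(mset))
    vals <- t(SummarizedExperiment::assay(mset, "value"))
    out <- cbind(data.frame(culture_id = colnames(mset)), cd, vals)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(trialsPath)) {
        tr <- t(SummarizedExperiment::assay(mset, "trials"))
        keep <- colSums(!is.na(tr)) > 0
        out <- cbind(data.frame(culture_id = colnames(mset)), cd,
                     tr[, keep, drop = FALSE])
        utils::write.table(out, trialsPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read / write a Z-score matrix as TSV (strains x parameters)
#'
#' @param path file path.
#' @param reference reference strain label recorded in the object.
#' @return \code{readZScoreMatrix}: a \linkS4class{ZScoreMatrix}.
#' @export
readZScoreMatrix <- function(path, reference = "wildtype") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    z <- as.matrix(df[, -1, drop = FALSE])
    rownames(z) <- df[[1]]
    methods::new("ZScoreMatrix", z = z, reference = reference,
                 dropped = character(0), provenance = "")
}

#' @rdname readZScoreMatrix
#' @param z a \linkS4class{ZScoreMatrix} (or plain matrix) to write.
#' @export
writeZScoreMatrix <- function(z, path) {
    m <- if (methods::is(z, "ZScoreMatrix")) zMatrix(z) else as.matrix(z)
    out <- cbind(data.frame(strain_id = rownames(m)), as.data.frame(m))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' One gene set per line: id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @param genomeCounts optional named integer vector of genome-wide
#'   annotation counts per set id; defaults to the set sizes.
#' @return A list of GO sets, each a list with \code{go_id},
#'   \code{description}, \code{genes}, \code{genome_count}.
#' @export
readGmt <- function(path, genomeCounts = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        genes <- unique(f[-(1:2)])
        gc <- if (!is.null(genomeCounts) && f[1] %in% names(genomeCounts))
            as.integer(genomeCounts[f[1]]) else length(genes)
        list(go_id = f[1], description = f[2], genes = genes,
             genome_count = gc)
    })
    names(out) <- vapply(out, `[[`, "", "go_id")
    out
}

#' Read a genetic-interaction table
#'
#' @param path TSV with columns \code{gene_a}, \code{gene_b},
#'   \code{epsilon}, \code{p_value}.
#' @return data.frame of interaction records.
#' @export
readInteractions <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_a", "gene_b", "epsilon", "p_value") %in% colnames(df)))
    df
}
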