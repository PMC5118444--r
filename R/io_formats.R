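# Readers and writers for the external formats the pipeline touches.
#
# Every interval held in memory by this package is 0-based half-open, so
# length == end - start with no off-by-one bookkeeping. GFF3/GTF (1-based
# inclusive) are shifted on read; report TSVs display 1-based inclusive
# coordinates to match Ensembl-style tables, and every writer states its
# convention in a header comment line.

#' Describe a genome as chromosome lengths and baseline copy numbers
#'
#' The baseline (expected) copy number is the ploidy against which CNV calls
#' are interpreted: members below baseline are losses, above are gains. For
#' male mammalian samples the X chromosome baseline is 1; autosomes default
#' to 2. Chromosomes named `"X"` or `"chrX"` get baseline 1 unless
#' `expected_copy_number` is supplied explicitly.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bases (> 0).
#' @param expected_copy_number optional integer vector of per-chromosome
#'   baselines (>= 1). Defaults to 2 for autosomes and 1 for X.
#' @return A `data.frame` with columns `chrom`, `length`,
#'   `expected_copy_number`.
#' @examples
#' genome_description(c("chr1", "chrX"), c(1e6, 5e5))
#' @export
genome_description <- function(chrom, length, expected_copy_number = NULL) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) {
    stop("duplicated chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  length <- as.numeric(length)
  if (any(is.na(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (is.null(expected_copy_number)) {
    expected_copy_number <- ifelse(chrom %in% c("X", "chrX"), 1L, 2L)
  }
  expected_copy_number <- as.integer(expected_copy_number)
  if (any(is.na(expected_copy_number)) || any(expected_copy_number < 1L)) {
    stop("expected_copy_number must be >= 1")
  }
  data.frame(chrom = chrom, length = length,
             expected_copy_number = rep_len(expected_copy_number, base::length(chrom)),
             stringsAsFactors = FALSE)
}

#' Read a genome description TSV
#'
#' Expects a header with columns `chrom`, `length` and optionally
#' `expected_copy_number`.
#'
#' @param path path to a tab-separated file.
#' @return A genome description `data.frame` (see [genome_description()]).
#' @export
read_genome_description <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("chrom", "length") %in% names(df))) {
    stop("genome description needs columns 'chrom' and 'length': ", path)
  }
  genome_description(df$chrom, df$length,
                     if ("expected_copy_number" %in% names(df))
                       df$expected_copy_number else NULL)
}

#' @rdname read_genome_description
#' @param genome a genome description `data.frame`.
#' @export
write_genome_description <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chromosome lengths in bases; baseline = expected copy number", con)
  utils::write.table(genome, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample CNV calls
#'
#' Consumes the output shape of a multi-sample read-depth CNV caller: one row
#' per sample-level call with an integer copy number. Two dialects are
#' supported:
#' \describe{
#'   \item{`bed_like`}{five whitespace/tab-separated columns without header:
#'     `sample chrom start end copy_number`, coordinates 0-based half-open
#'     (BED convention).}
#'   \item{`tsv_with_header`}{a tab-separated file with a header naming (at
#'     least) `sample`, `chrom`, `start`, `end`, `copy_number`; coordinates
#'     0-based half-open.}
#' }
#'
#' @param path input file.
#' @param dialect `"bed_like"` or `"tsv_with_header"`.
#' @return A `data.frame` of calls with columns `sample`, `chrom`, `start`,
#'   `end`, `copy_number`, sorted by (chrom, start, end, sample).
#' @export
read_cnv_calls <- function(path, dialect = c("bed_like", "tsv_with_header")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (dialect == "tsv_with_header") {
    first <- which(keep)[1]
    if (is.na(first)) return(empty_cnv_calls())
    hdr <- strsplit(lines[first], "\t", fixed = TRUE)[[1]]
    need <- c("sample", "chrom", "start", "end", "copy_number")
    idx <- match(need, hdr)
    if (anyNA(idx)) {
      stop("missing column(s) in ", path, ": ",
           paste(need[is.na(idx)], collapse = ", "))
    }
    keep[first] <- FALSE
  } else {
    idx <- 1:5
  }
  rows <- which(keep)
  if (!length(rows)) return(empty_cnv_calls())
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]),
                       if (dialect == "bed_like") "[ \t]+" else "\t")[[1]]
    if (length(fields) < max(idx)) {
      stop("malformed row at line ", i, " of ", path,
           ": expected >= ", max(idx), " fields, got ", length(fields))
    }
    fields[idx]
  })
  m <- do.call(rbind, parsed)  # columns already in canonical order via idx
  calls <- data.frame(sample = m[, 1], chrom = m[, 2],
                      start = suppressWarnings(as.numeric(m[, 3])),
                      end = suppressWarnings(as.numeric(m[, 4])),
                      copy_number = suppressWarnings(as.integer(m[, 5])),
                      stringsAsFactors = FALSE)
  bad <- which(is.na(calls$start) | is.na(calls$end) | is.na(calls$copy_number))
  if (length(bad)) {
    stop("malformed row at line ", rows[bad[1]], " of ", path,
         ": non-numeric start/end/copy_number")
  }
  bad <- which(calls$end <= calls$start)
  if (length(bad)) {
    stop("invalid interval (end <= start) at line ", rows[bad[1]], " of ", path)
  }
  bad <- which(calls$copy_number < 0L)
  if (length(bad)) {
    stop("negative copy number at line ", rows[bad[1]], " of ", path)
  }
  sort_cnv_calls(calls)
}

empty_cnv_calls <- function() {
  data.frame(sample = character(), chrom = character(),
             start = numeric(), end = numeric(),
             copy_number = integer(), stringsAsFactors = FALSE)
}

sort_cnv_calls <- function(calls) {
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$sample), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Write per-sample CNV calls
#'
#' Writes the `tsv_with_header` dialect read back by [read_cnv_calls()]
#' (0-based half-open coordinates).
#'
#' @param calls a CNV call `data.frame`.
#' @param path output path.
#' @export
write_cnv_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open", con)
  utils::write.table(
    calls[, c("sample", "chrom", "start", "end", "copy_number")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3, GTF or BED
#'
#' Only `gene` features are retained from GFF3/GTF (the number skipped is
#' reported via `message()`); BED rows are all taken as genes. Coordinates
#' are unified to 0-based half-open. `gene_id` is taken from the `gene_id`
#' attribute, falling back to `ID`/`Name` for GFF3 and the BED name column;
#' `biotype` from `biotype`/`gene_biotype` (`"unknown"` when absent).
#'
#' @param path input file; format inferred from the extension unless given.
#' @param format `"auto"`, `"gff3"`, `"gtf"` or `"bed"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gff = "gff3", gff3 = "gff3", gtf = "gtf", bed = "bed",
                     stop("cannot infer format from extension: ", path))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene_", seq_along(gr))
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = as.numeric(GenomicRanges::end(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      biotype = "unknown", stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
    meta <- S4Vectors::mcols(gr)
    if (!is.null(meta$type)) {
      is_gene <- as.character(meta$type) == "gene"
      n_skip <- sum(!is_gene)
      if (n_skip > 0) message(n_skip, " non-gene feature(s) skipped")
      gr <- gr[is_gene]
      meta <- S4Vectors::mcols(gr)
    }
    pick <- function(...) {
      for (nm in c(...)) {
        if (!is.null(meta[[nm]])) return(as.character(meta[[nm]]))
      }
      NULL
    }
    ids <- pick("gene_id", "ID", "Name")
    if (is.null(ids) || anyNA(ids)) {
      stop("gene feature without a gene_id/ID attribute in ", path)
    }
    biotype <- pick("biotype", "gene_biotype")
    if (is.null(biotype)) biotype <- rep("unknown", length(gr))
    out <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = as.numeric(GenomicRanges::end(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      biotype = biotype, stringsAsFactors = FALSE)
  }
  out$strand[!out$strand %in% c("+", "-")] <- "."
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as minimal GFF3
#'
#' Emits one `gene` feature per row with `ID` and `biotype` attributes,
#' 1-based inclusive coordinates per the GFF3 specification. Readable back
#' with [read_gene_models()].
#'
#' @param genes gene-model `data.frame` (0-based half-open, as returned by
#'   [read_gene_models()]).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tcnvrtools\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                     genes$chrom, as.integer(genes$start) + 1L,
                     as.integer(genes$end), genes$strand, genes$gene_id,
                     genes$biotype), con)
  invisible(path)
}

#' Write a CNVR report
#'
#' The TSV displays 1-based inclusive coordinates (Ensembl-table style); the
#' optional BED track keeps the native 0-based half-open convention. Member
#' calls are serialized as a comma-separated `sample:copy_number` list.
#'
#' @param cnvr_set a `cnvr_set` (see [merge_cnvs()]).
#' @param path output TSV path.
#' @param bed_path optional BED output path.
#' @export
write_cnvr_report <- function(cnvr_set, path, bed_path = NULL) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  cnvrs <- cnvr_set$cnvrs
  calls <- cnvr_set$calls
  members <- vapply(cnvrs$cnvr_id, function(id) {
    m <- calls[calls$cnvr_id == id, , drop = FALSE]
    paste(sprintf("%s:%d", m$sample, m$copy_number), collapse = ",")
  }, character(1))
  out <- data.frame(cnvr_id = cnvrs$cnvr_id, chrom = cnvrs$chrom,
                    start = as.integer(cnvrs$start) + 1L,
                    end = as.integer(cnvrs$end),
                    state = if (!is.null(cnvrs$state)) cnvrs$state else NA,
                    n_samples = cnvrs$n_samples, members = members,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines("# coordinates: 1-based inclusive; members: sample:copy_number", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(bed_path)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t%d",
                   cnvrs$chrom, as.integer(cnvrs$start),
                   as.integer(cnvrs$end), cnvrs$cnvr_id, cnvrs$n_samples)
    writeLines(c("# coordinates: 0-based half-open (BED)", bed), bed_path)
  }
  invisible(path)
}

#' Read back a CNVR report written by [write_cnvr_report()]
#'
#' @param path a CNVR report TSV.
#' @return A `cnvr_set` equivalent to the one written (member call order may
#'   differ only in row order).
#' @export
read_cnvr_report <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  n_calls <- vapply(df$members, function(m) {
    if (!nzchar(m)) 0L else length(strsplit(m, ",", fixed = TRUE)[[1]])
  }, integer(1), USE.NAMES = FALSE)
  cnvrs <- data.frame(cnvr_id = as.character(df$cnvr_id), chrom = df$chrom,
                      start = df$start - 1, end = as.numeric(df$end),
                      n_samples = df$n_samples, n_calls = n_calls,
                      stringsAsFactors = FALSE)
  if ("state" %in% names(df) && !all(is.na(df$state))) cnvrs$state <- df$state
  calls <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    if (!nzchar(df$members[i])) return(NULL)
    parts <- strsplit(strsplit(df$members[i], ",", fixed = TRUE)[[1]],
                      ":", fixed = TRUE)
    data.frame(sample = vapply(parts, `[`, "", 1),
               chrom = df$chrom[i], start = df$start[i] - 1,
               end = as.numeric(df$end[i]),
               copy_number = as.integer(vapply(parts, `[`, "", 2)),
               cnvr_id = as.character(df$cnvr_id[i]), stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- cbind(empty_cnv_calls(),
                   data.frame(cnvr_id = character(), stringsAsFactors = FALSE))
  }
  new_cnvr_set(cnvrs, calls)
}

#' Read a term-to-gene annotation table
#'
#' @param path two-column TSV with header `term_id`, `gene_id` (one row per
#'   annotation).
#' @param meta_path optional TSV with header `term_id`, `term_name`, `aspect`.
#' @return A list with `term2gene` (data.frame) and `meta` (data.frame or
#'   NULL), class `annotation_table`.
#' @export
read_annotation_table <- function(path, meta_path = NULL) {
  t2g <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("term_id", "gene_id") %in% names(t2g))) {
    stop("annotation table needs columns term_id and gene_id: ", path)
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, comment.char = "#",
                              quote = "")
  }
  structure(list(term2gene = unique(t2g[, c("term_id", "gene_id")]),
                 meta = meta), class = "annotation_table")
}

#' Read one expression experiment (matrix + sample manifest)
#'
#' The matrix is a TSV with a `gene_id` column followed by one column per
#' sample. The manifest is a TSV with header `sample`, `tissue` mapping every
#' matrix column to a tissue.
#'
#' @param matrix_path gene-by-sample expression TSV.
#' @param manifest_path sample manifest TSV.
#' @param experiment_id identifier used in reports.
#' @param platform `"microarray_upc"` (values in \[0,1\]) or `"rnaseq_fpkm"`
#'   (non-negative FPKM/RPKM).
#' @return An `expression_experiment` list: `experiment_id`, `platform`,
#'   `values` (numeric matrix, genes x samples), `tissue` (per-sample vector).
#' @export
read_expression_experiment <- function(matrix_path, manifest_path,
                                       experiment_id,
                                       platform = c("microarray_upc",
                                                    "rnaseq_fpkm")) {
  platform <- match.arg(platform)
  df <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id: ", matrix_path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  manifest <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, comment.char = "#")
  idx <- match(colnames(values), manifest$sample)
  if (anyNA(idx)) {
    stop("samples missing from manifest: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "))
  }
  expression_experiment(experiment_id, platform, values, manifest$tissue[idx])
}

#' Construct an expression experiment in memory
#'
#' @inheritParams read_expression_experiment
#' @param values numeric gene-by-sample matrix with gene ids as rownames.
#' @param tissue character vector, one tissue per sample column.
#' @export
expression_experiment <- function(experiment_id, platform, values, tissue) {
  platform <- match.arg(platform, c("microarray_upc", "rnaseq_fpkm"))
  if (length(tissue) != ncol(values)) {
    stop("one tissue per sample column required")
  }
  if (platform == "microarray_upc" &&
      (min(values) < 0 || max(values) > 1)) {
    stop("UPC values must lie in [0, 1]")
  }
  if (platform == "rnaseq_fpkm" && min(values) < 0) {
    stop("FPKM/RPKM values must be non-negative")
  }
  structure(list(experiment_id = experiment_id, platform = platform,
                 values = values, tissue = as.character(tissue)),
            class = "expression_experiment")
}

#' Write an expression experiment to matrix + manifest TSVs
#'
#' @param experiment an `expression_experiment`.
#' @param matrix_path,manifest_path output paths.
#' @export
write_expression_experiment <- function(experiment, matrix_path, manifest_path) {
  df <- data.frame(gene_id = rownames(experiment$values),
                   experiment$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(experiment$values),
                                tissue = experiment$tissue),
                     manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read an undirected interaction edge list
#'
#' Two-column (plus optional `score`, ignored) TSV with header
#' `gene1`, `gene2`. Self-loops are dropped and unordered duplicates
#' collapsed by [compute_degrees()]; this reader only validates shape.
#'
#' @param path edge-list TSV.
#' @return A `data.frame` with columns `gene1`, `gene2`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      stringsAsFactors = FALSE))
  }
  hdr <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  if (!all(c("gene1", "gene2") %in% hdr)) {
    stop("edge list needs header columns gene1 and gene2: ", path)
  }
  i1 <- match("gene1", hdr); i2 <- match("gene2", hdr)
  rows <- body[-1]
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  short <- which(lengths(fields) < max(i1, i2))
  if (length(short)) {
    stop("malformed edge row at line ", rows[short[1]], " of ", path)
  }
  data.frame(gene1 = vapply(fields, `[`, "", i1),
             gene2 = vapply(fields, `[`, "", i2), stringsAsFactors = FALSE)
}

#' Read paired ortholog coding sequences from two FASTA files
#'
#' Records are matched by order; ids are taken from the first file.
#'
#' @param query_path,ortholog_path FASTA files with matched record order.
#' @return A `data.frame` with columns `gene_id`, `query_cds`,
#'   `ortholog_cds`.
#' @export
read_ortholog_pairs <- function(query_path, ortholog_path) {
  q <- Biostrings::readDNAStringSet(query_path)
  o <- Biostrings::readDNAStringSet(ortholog_path)
  if (length(q) != length(o)) {
    stop("paired FASTA files differ in record count (",
         length(q), " vs ", length(o), ")")
  }
  out <- data.frame(gene_id = sub("\\s.*$", "", names(q)),
                    query_cds = unname(as.character(q)),
                    ortholog_cds = unname(as.character(o)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write ortholog pairs to two FASTA files
#'
#' @param pairs data.frame as returned by [read_ortholog_pairs()].
#' @param query_path,ortholog_path output FASTA paths.
#' @export
write_ortholog_pairs <- function(pairs, query_path, ortholog_path) {
  q <- Biostrings::DNAStringSet(pairs$query_cds)
  o <- Biostrings::DNAStringSet(pairs$ortholog_cds)
  names(q) <- pairs$gene_id
  names(o) <- pairs$gene_id
  Biostrings::writeXStringSet(q, query_path)
  Biostrings::writeXStringSet(o, ortholog_path)
  invisible(query_path)
}
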