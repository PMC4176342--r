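#' Read aligned single-end reads from BED6 or minimal SAM
#'
#' Converts aligned reads into the package's internal representation: a
#' tibble with columns `chrom`, `start` (0-based leftmost coordinate),
#' `length` (bp) and `strand` (`"+"`/`"-"`), carrying the total mapped read
#' count as an attribute (see [total_mapped()]).
#'
#' BED6 is 0-based half-open, so `length = end - start`. SAM support is
#' deliberately minimal: only FLAG, RNAME, POS and the read length (from the
#' CIGAR sum of M/I/S/=/X operations, or `nchar(SEQ)` when the CIGAR is `*`)
#' are used; POS is converted from 1-based to 0-based, FLAG bit 0x10 gives
#' the minus strand, and unmapped records (0x4) are skipped and not counted
#' in `total_mapped`.
#'
#' @param path Path to the alignment file.
#' @param format `"bed"` or `"sam"`.
#' @return Tibble of reads with attribute `total_mapped`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chrI\t100\t150\tr1\t0\t+", f)
#' read_alignments(f, "bed")
#' @export
read_alignments <- function(path, format = c("bed", "sam")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reads <- switch(format, bed = read_bed_reads(path), sam = read_sam_reads(path))
  reads
}

#' Total mapped reads behind a read set or track
#'
#' @param x A reads tibble from [read_alignments()] / [simulate_reads()]
#'   (attribute set at creation) or a `coverage_track`.
#' @return Integer count; for a plain tibble without the attribute, the
#'   number of rows.
#' @export
total_mapped <- function(x) {
  if (inherits(x, "coverage_track")) return(x$total_mapped)
  tm <- attr(x, "total_mapped")
  if (is.null(tm)) nrow(x) else tm
}

new_reads <- function(chrom = character(), start = integer(),
                      length = integer(), strand = character(),
                      total_mapped = NULL) {
  out <- tibble(chrom = as.character(chrom), start = as.integer(start),
                length = as.integer(length), strand = as.character(strand))
  attr(out, "total_mapped") <- as.integer(total_mapped %||% nrow(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_bed_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(new_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("malformed BED line %d: fewer than 6 columns",
                  which(nf < 6)[1]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  strand <- m[, 6]
  bad <- is.na(start) | is.na(end) | end <= start | !(strand %in% c("+", "-"))
  if (any(bad)) {
    abort(sprintf("malformed BED line %d: bad coordinates or strand",
                  which(bad)[1]))
  }
  new_reads(m[, 1], start, end - start, strand)
}

cigar_query_length <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(parts) {
    if (length(parts) == 0) return(NA_integer_)
    op <- substring(parts, nchar(parts), nchar(parts))
    n <- as.integer(substring(parts, 1, nchar(parts) - 1))
    sum(n[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
}

read_sam_reads <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "@")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(new_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10)) {
    abort(sprintf("malformed SAM line %d: fewer than 10 fields",
                  lineno[which(nf < 10)[1]]))
  }
  flag <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  if (any(is.na(flag)) || any(is.na(pos))) {
    abort(sprintf("malformed SAM line %d: non-numeric FLAG or POS",
                  lineno[which(is.na(flag) | is.na(pos))[1]]))
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  fields <- fields[mapped]; flag <- flag[mapped]; pos <- pos[mapped]
  lineno <- lineno[mapped]
  if (length(fields) == 0) return(new_reads())
  rname <- vapply(fields, `[`, "", 3)
  cigar <- vapply(fields, `[`, "", 6)
  seq <- vapply(fields, `[`, "", 10)
  len <- cigar_query_length(cigar)
  use_seq <- cigar == "*"
  len[use_seq] <- nchar(seq[use_seq])
  bad <- is.na(len) | len < 1 | (use_seq & seq == "*")
  if (any(bad)) {
    abort(sprintf("malformed SAM line %d: cannot determine read length",
                  lineno[which(bad)[1]]))
  }
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  new_reads(rname, pos - 1L, len, strand)
}

#' Write reads as BED6
#'
#' @param reads Reads tibble (`chrom`, `start`, `length`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\tr%d\t0\t%s",
                   reads$chrom, reads$start, reads$start + reads$length,
                   seq_len(nrow(reads)), reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` features from a GFF3 file into a tibble with columns
#' `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open), `tss`,
#' `cre_site` and `atf1_dependent`. GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open; the TSS is the feature start for `+`
#' genes and `end - 1` for `-` genes. The CRE/TF-binding-site midpoint is
#' carried as a 1-based `cre_site` attribute on the gene record; records
#' without it get `cre_site = NA` (no error). A boolean `atf1_dependent`
#' attribute marks TF-dependent genes (default `FALSE`).
#'
#' @param path Path to the GFF3 file.
#' @return Tibble of gene models.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!is.null(df$type)) df <- df[as.character(df$type) == "gene", , drop = FALSE]
  if (nrow(df) == 0) return(empty_gene_models())
  strand <- as.character(df$strand)
  if (any(strand == "*")) abort("gene model without strand in GFF3")
  start0 <- df$start - 1L   # GFF3 is 1-based inclusive
  end0 <- df$end            # half-open end
  ids <- df$ID %||% df$Name %||% df$gene_id
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_len(nrow(df)))
  cre <- df$cre_site %||% rep(NA_character_, nrow(df))
  cre0 <- suppressWarnings(as.integer(cre)) - 1L
  dep <- df$atf1_dependent %||% rep("false", nrow(df))
  dep <- tolower(as.character(dep)) %in% c("true", "1", "yes")
  dep[is.na(dep)] <- FALSE
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(df$seqnames),
    strand = strand,
    start = start0,
    end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    cre_site = cre0,
    atf1_dependent = dep
  )
}

empty_gene_models <- function() {
  tibble(gene_id = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(), tss = integer(),
         cre_site = integer(), atf1_dependent = logical())
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: 0-based half-open coordinates are
#' written as 1-based inclusive, with `cre_site` (1-based) and
#' `atf1_dependent` carried as attributes.
#'
#' @param genes Gene model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  attrs <- sprintf("ID=%s;atf1_dependent=%s", genes$gene_id,
                   tolower(as.character(genes$atf1_dependent)))
  has_cre <- !is.na(genes$cre_site)
  attrs[has_cre] <- sprintf("%s;cre_site=%d", attrs[has_cre],
                            genes$cre_site[has_cre] + 1L)
  lines <- sprintf("%s\tnucbarrier\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom, genes$start + 1L, genes$end,
                   genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a coverage track as fixedStep WIG
#'
#' One `fixedStep` block per chromosome (`start=1 step=1`, i.e. track
#' position 0 maps to WIG coordinate 1). Values are rendered with at most 6
#' significant digits, so a write/read round trip agrees within 1e-6
#' relative. Zero-length chromosomes are omitted entirely.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(track$values)) {
    v <- track$values[[nm]]
    if (length(v) == 0) next
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", nm), con)
    writeLines(sprintf("%.6g", v), con)
  }
  invisible(path)
}

#' Read a fixedStep WIG file into a coverage track
#'
#' Only `fixedStep` blocks with `step=1` are supported (the flavor
#' [write_wig()] emits). Blocks for the same chromosome are concatenated at
#' the declared starts; unspecified leading positions are zero.
#'
#' @param path Path to the WIG file.
#' @param state Processing state to stamp on the result.
#' @return A `coverage_track`.
#' @export
read_wig <- function(path, state = "raw") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  is_hdr <- startsWith(lines, "fixedStep")
  if (length(lines) > 0 && !is_hdr[1]) abort("WIG file must start with a fixedStep header")
  values <- list()
  hdr_idx <- which(is_hdr)
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    hdr <- lines[hdr_idx[i]]
    get_field <- function(key) {
      m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
      if (length(m) == 0) return(NA_character_)
      sub(paste0(key, "="), "", m)
    }
    chrom <- get_field("chrom")
    start1 <- as.integer(get_field("start"))
    step <- get_field("step")
    if (!is.na(step) && step != "1") abort("only step=1 fixedStep WIG is supported")
    body <- lines[seq(hdr_idx[i] + 1L, bounds[i + 1] - 1L)]
    v <- as.numeric(body)
    if (anyNA(v)) abort(sprintf("non-numeric WIG value in block for %s", chrom))
    cur <- values[[chrom]] %||% numeric(0)
    need <- start1 - 1L + length(v)
    if (length(cur) < need) cur <- c(cur, numeric(need - length(cur)))
    cur[seq(start1, start1 + length(v) - 1L)] <- v
    values[[chrom]] <- cur
  }
  coverage_track(values, state = state)
}
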