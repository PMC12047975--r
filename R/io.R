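#' Read a strain x marker genotype table
#'
#' The dialect mirrors GeneNetwork-style genotype files transposed to one
#' row per strain: leading `#chr`, `#cM`, `#Mb` header lines carry the map,
#' a `strain` header row carries marker names, and cells hold the founder
#' codes `B`/`D`/`H`/`U` (or, equivalently, numeric `0`/`1`/`0.5`/`NA`).
#' `B` codes the first founder (0), `D` the second (1), `H` heterozygous
#' (0.5) and `U` unknown (`NA`).
#'
#' @param path file path.
#' @return A [genotype_matrix()].
#' @seealso [write_geno_tsv()]
#' @export
read_geno_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  body <- lines[!hdr]
  if (length(body) < 2L) stop("genotype file needs a header row and >=1 strain")
  get_meta <- function(tag) {
    row <- meta[startsWith(meta, paste0("#", tag, "\t"))]
    if (length(row) != 1L) stop("missing #", tag, " header line")
    strsplit(row, "\t", fixed = TRUE)[[1]][-1]
  }
  chr <- get_meta("chr")
  cM <- as.numeric(get_meta("cM"))
  Mb <- as.numeric(get_meta("Mb"))
  cells <- strsplit(body, "\t", fixed = TRUE)
  markers <- cells[[1]][-1]
  map <- founder_map(markers, chr, cM, Mb)
  strains <- vapply(cells[-1], `[`, "", 1L)
  raw <- t(vapply(cells[-1], function(x) x[-1], character(length(markers))))
  code <- function(x) {
    out <- suppressWarnings(as.numeric(x))
    txt <- is.na(out) & !(x %in% c("NA", ""))
    out[txt] <- c(B = 0, D = 1, H = 0.5, U = NA)[x[txt]]
    out
  }
  geno <- matrix(code(raw), nrow = length(strains),
                 dimnames = list(strains, markers))
  genotype_matrix(geno, map)
}

#' Write a genotype matrix in the strain x marker TSV dialect
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @param codes write founder letters (`TRUE`, default) or numeric codes.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(x, path, codes = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"))
  m <- x$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("#chr", m$chr), collapse = "\t"),
               paste(c("#cM", m$cM), collapse = "\t"),
               paste(c("#Mb", m$Mb), collapse = "\t"),
               paste(c("strain", m$marker), collapse = "\t")), con)
  body <- x$geno
  if (codes) {
    lut <- function(v) ifelse(is.na(v), "U",
                       ifelse(v == 0, "B", ifelse(v == 1, "D", "H")))
    body <- matrix(lut(x$geno), nrow = nrow(x$geno),
                   dimnames = dimnames(x$geno))
  }
  writeLines(paste(rownames(body),
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read/write plain TSV tables
#'
#' Thin wrappers fixing the dialect used throughout the package: tab
#' separated, header row, no quoting, no row names.
#'
#' @param path file path.
#' @return `read_tsv_table()` returns a `data.frame`; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}
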