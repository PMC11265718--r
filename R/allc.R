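#' Classify cytosine sequence contexts
#'
#' Maps a C-initial trinucleotide (read 5'->3' on the cytosine's own strand)
#' to its methylation context class and, for CHG, its subcontext.
#'
#' A cytosine is CG if the second base is G; CHG if the second base is
#' H (A, C or T) and the third base is G; otherwise CHH. CHG sites split
#' into CWG (W = A or T; the symmetric triplet preferred by the plant CHG
#' methyltransferase CMT3) and CCG (whose methylation additionally depends
#' on MET1).
#'
#' @param trinuc Character vector of 3-mers over A/C/G/T, each starting
#'   with C.
#' @return A `data.table` with columns `context` (`"CG"`, `"CHG"`, `"CHH"`)
#'   and `subcontext` (`"CWG"`, `"CCG"`, or `NA` outside CHG), one row per
#'   input trinucleotide.
#' @examples
#' classify_context(c("CGA", "CAG", "CCG", "CTT"))
#' @export
classify_context <- function(trinuc) {
  if (length(trinuc) == 0L) {
    return(data.table::data.table(context = character(), subcontext = character()))
  }
  if (anyNA(trinuc) || any(nchar(trinuc) != 3L)) {
    stop("trinucleotides must be non-missing 3-mers")
  }
  if (any(!grepl("^C[ACGT][ACGT]$", trinuc))) {
    bad <- trinuc[!grepl("^C[ACGT][ACGT]$", trinuc)]
    stop("invalid trinucleotide(s): must start with C and contain only A/C/G/T: ",
         paste(utils::head(unique(bad), 5L), collapse = ", "))
  }
  b2 <- substr(trinuc, 2L, 2L)
  b3 <- substr(trinuc, 3L, 3L)
  context <- data.table::fifelse(b2 == "G", "CG",
              data.table::fifelse(b3 == "G", "CHG", "CHH"))
  subcontext <- rep(NA_character_, length(trinuc))
  chg <- context == "CHG"
  subcontext[chg] <- data.table::fifelse(b2[chg] %in% c("A", "T"), "CWG", "CCG")
  data.table::data.table(context = context, subcontext = subcontext)
}

#' Validate an allc table
#'
#' Checks the structural invariants of a per-cytosine methylation table:
#' required columns, `mc <= cov`, non-negative counts, strands in {+,-}.
#'
#' @param allc A `data.table` of per-cytosine records.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_allc <- function(allc) {
  req <- c("chrom", "pos", "strand", "trinuc", "mc", "cov")
  miss <- setdiff(req, names(allc))
  if (length(miss)) stop("allc table missing column(s): ", paste(miss, collapse = ", "))
  if (any(allc$mc < 0L) || any(allc$cov < 0L)) stop("negative read counts")
  bad <- which(allc$mc > allc$cov)
  if (length(bad)) {
    stop("mc > cov at record(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(!allc$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(allc)
}

#' Read a per-cytosine methylation call table (allc dialect)
#'
#' Parses the 7-column tab-separated allc format: chromosome, 1-based
#' position, strand, trinucleotide context (on the site's own strand),
#' methylated-read count, total-read count, call flag. The context class
#' and subcontext are recomputed from the trinucleotide rather than
#' trusted from the file.
#'
#' @param path Path to a tab-separated allc file (no header).
#' @return A `data.table` with columns `chrom`, `pos`, `strand`, `trinuc`,
#'   `context`, `subcontext`, `mc`, `cov`, `called` (logical, `NA` when the
#'   call flag is absent).
#' @seealso [write_allc()]
#' @export
read_allc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = c(1, 3, 4)),
                      na.strings = c("NA", ".", "")),
    error = function(e) stop("failed to parse allc file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      trinuc = character(), context = character(), subcontext = character(),
      mc = integer(), cov = integer(), called = logical()))
  }
  if (ncol(dt) < 6L || ncol(dt) > 7L) {
    stop("allc file '", path, "' must have 6 or 7 tab-separated columns, found ",
         ncol(dt))
  }
  if (ncol(dt) == 6L) dt[, V7 := NA_integer_]
  data.table::setnames(dt, c("chrom", "pos", "strand", "trinuc", "mc", "cov", "called"))
  for (col in c("pos", "mc", "cov")) {
    v <- dt[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("malformed allc line ", if (is.na(bad)) "?" else bad,
           " in '", path, "': non-numeric '", col, "' field")
    }
    data.table::set(dt, j = col, value = as.integer(v))
  }
  bad <- which(dt$mc > dt$cov)
  if (length(bad)) {
    stop("allc line ", bad[1], " in '", path, "': mc (", dt$mc[bad[1]],
         ") exceeds cov (", dt$cov[bad[1]], ")")
  }
  ctx <- classify_context(dt$trinuc)
  dt[, `:=`(context = ctx$context, subcontext = ctx$subcontext)]
  dt[, called := as.logical(called)]
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "trinuc", "context",
                                "subcontext", "mc", "cov", "called"))
  validate_allc(dt)
  dt[]
}

#' Write a per-cytosine methylation call table
#'
#' Writes records in the 7-column allc dialect, sorted by chromosome,
#' position and strand. The call flag is written as 1/0 (empty when unset).
#'
#' @param allc A valid allc `data.table` (see [read_allc()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allc <- function(allc, path) {
  validate_allc(allc)
  out <- data.table::as.data.table(allc)[, .(chrom, pos, strand, trinuc, mc, cov,
    called = if ("called" %in% names(allc)) as.integer(called) else NA_integer_)]
  if (!is.character(out$chrom)) out[, chrom := as.character(chrom)]
  data.table::setorder(out, chrom, pos, strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Pooled weighted methylation level
#'
#' The coverage-weighted methylation level of a set of sites:
#' sum of methylated reads / sum of total reads.
#'
#' @param mc Methylated-read counts.
#' @param cov Total-read counts.
#' @return A single fraction, `NA` when total coverage is zero.
#' @export
weighted_level <- function(mc, cov) {
  tot <- sum(as.numeric(cov))
  if (tot == 0) return(NA_real_)
  sum(as.numeric(mc)) / tot
}
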