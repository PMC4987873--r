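# Readers and writers: MGF spectra, protein sequences, PSM tables.

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE`, `TITLE` and
#' `RTINSECONDS` headers. A second `PEPMASS` field (precursor intensity) is
#' ignored. Blocks without a `CHARGE` line default to 2+ with a warning, since
#' most tryptic glycopeptide precursors are at least doubly charged.
#'
#' @param path MGF file path.
#' @return List of [new_spectrum()] objects (peaks sorted ascending by m/z).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!length(lines) || !any(nzchar(lines))) {
    warning("empty MGF file: ", path, call. = FALSE)
    return(list())
  }
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("unpaired BEGIN IONS/END IONS in ", path, call. = FALSE)
  spectra <- vector("list", length(begins))
  n_nocharge <- 0L
  for (k in seq_along(begins)) {
    body <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    body <- body[nzchar(body) & !startsWith(body, "#")]
    is_kv <- grepl("^[A-Za-z]+=", body)
    kv <- body[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[A-Za-z]+=", "", kv)
    get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    pepmass <- get("PEPMASS")
    if (is.na(pepmass))
      stop("MGF block starting at line ", begins[k], " has no PEPMASS", call. = FALSE)
    precursor_mz <- as.numeric(strsplit(pepmass, "[ \t]+")[[1L]][1L])
    ch <- get("CHARGE")
    if (is.na(ch)) {
      charge <- 2L
      n_nocharge <- n_nocharge + 1L
    } else {
      charge <- as.integer(gsub("[^0-9]", "", ch))
    }
    title <- get("TITLE")
    if (is.na(title)) title <- sprintf("index=%d", k)
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    pk <- body[!is_kv]
    if (length(pk)) {
      fields <- strsplit(pk, "[ \t]+")
      mz <- as.numeric(vapply(fields, `[`, "", 1L))
      it <- as.numeric(vapply(fields, `[`, "", 2L))
      if (anyNA(mz) || anyNA(it))
        stop("unparseable peak line in MGF block starting at line ", begins[k],
             call. = FALSE)
      peaks <- cbind(mz = mz, intensity = it)
    } else {
      peaks <- matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("mz", "intensity")))
    }
    spectra[[k]] <- new_spectrum(title, precursor_mz, charge, peaks, rt = rt)
  }
  if (n_nocharge)
    warning(n_nocharge, " MGF block(s) lacked CHARGE; defaulted to 2+", call. = FALSE)
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `glyco_spectrum` (or in silico spectrum) objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (!length(spectra)) stop("no spectra to write", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.3f", sp$rt), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.6f", sp$peaks[, "mz"], sp$peaks[, "intensity"]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read protein sequences (FASTA or one sequence per line)
#'
#' Sequences are uppercased; `*` and whitespace are stripped. At most
#' `max_count` sequences are accepted, mirroring the targeted-analysis cap of
#' 10 proteins per run.
#'
#' @param path FASTA file, or plain text with one sequence per line.
#' @param max_count Maximum number of sequences.
#' @return Named character vector (accession -> sequence).
#' @export
read_protein_sequences <- function(path, max_count = 10L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character())
  if (startsWith(lines[1L], ">")) {
    hdr <- grepl("^>", lines)
    acc <- sub("^>\\s*", "", lines[hdr])
    acc <- vapply(strsplit(acc, "[ \t]"), `[`, "", 1L)
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
    names(seqs) <- acc
  } else {
    seqs <- lines
    names(seqs) <- sprintf("seq%02d", seq_along(seqs))
  }
  if (length(seqs) > max_count)
    stop("too many protein sequences (", length(seqs), "); at most ", max_count,
         " are allowed per targeted analysis", call. = FALSE)
  seqs <- toupper(gsub("[*[:space:]]", "", seqs))
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[[i]], "")[[1L]], names(amino_acid_masses()))
    if (length(bad))
      stop("non-amino-acid character(s) in sequence '", names(seqs)[i], "': ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Read a peptide-spectrum-match table
#'
#' Engine-agnostic TSV with mandatory columns `title`, `peptide`, `protein`,
#' `score` and optional `evalue`, `rt`. Rows whose `score` cannot be parsed
#' are skipped with a warning.
#'
#' @param path TSV path.
#' @return data.frame of PSM records.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  mandatory <- c("title", "peptide", "protein", "score")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("PSM table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$score <- suppressWarnings(as.numeric(df$score))
  df$evalue <- if ("evalue" %in% names(df))
    suppressWarnings(as.numeric(df$evalue)) else NA_real_
  df$rt <- if ("rt" %in% names(df))
    suppressWarnings(as.numeric(df$rt)) else NA_real_
  bad <- is.na(df$score) | !nzchar(df$title)
  if (any(bad))
    warning(sum(bad), " PSM row(s) skipped (unparseable score or empty title)",
            call. = FALSE)
  df <- df[!bad, c("title", "peptide", "protein", "score", "evalue", "rt"),
           drop = FALSE]
  rownames(df) <- NULL
  df
}
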