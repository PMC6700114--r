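#' Download a genome FASTA from NCBI by accession
#'
#' Fetches a nucleotide record through the NCBI E-utilities efetch endpoint
#' and caches it under `dest_dir`; an existing cached copy is reused.
#' Needed only for workflows that validate site counts against published
#' genomes — everything else in the package runs on local or synthetic
#' input.
#'
#' @param accession NCBI nucleotide accession (e.g. `"CP031054"`).
#' @param dest_dir cache directory (default `tempdir()`).
#' @param timeout download timeout in seconds.
#' @return path to the FASTA file.
#' @export
fetch_genome <- function(accession, dest_dir = tempdir(), timeout = 300) {
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dest_dir, paste0(accession, ".fasta"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession,
                "&rettype=fasta&retmode=text")
  old <- options(timeout = timeout)
  on.exit(options(old))
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE,
                                          mode = "wb"),
                     error = function(e) {
                       unlink(dest)
                       stop("could not download ", accession, " from NCBI: ",
                            conditionMessage(e), call. = FALSE)
                     })
  if (!file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("download of ", accession, " produced no data", call. = FALSE)
  }
  dest
}
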