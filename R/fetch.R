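#' Locate or download a deposited structure
#'
#' Looks for `<id>.cif` (or `.pdb`) in `cache_dir`, then attempts a download
#' from the wwPDB/RCSB file servers. Returns `NULL` with a warning when the
#' file is unavailable (e.g. offline), so callers can degrade explicitly
#' rather than crash.
#'
#' @param id 4-character PDB accession (e.g. `"7XCE"`).
#' @param cache_dir Directory searched first and used to store downloads.
#' @return Path to the structure file, or `NULL` if unavailable.
#' @export
fetch_structure_file <- function(id,
                                 cache_dir = tools::R_user_dir("ankgroove",
                                                               "cache")) {
  id <- toupper(id)
  for (ext in c(".cif", ".pdb", ".ent")) {
    p <- file.path(cache_dir, paste0(id, ext))
    if (file.exists(p)) return(p)
    p2 <- file.path(cache_dir, paste0(tolower(id), ext))
    if (file.exists(p2)) return(p2)
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(id, ".cif"))
  urls <- c(sprintf("https://files.rcsb.org/download/%s.cif", id),
            sprintf("https://www.ebi.ac.uk/pdbe/entry-files/download/%s.cif",
                    tolower(id)))
  for (u in urls) {
    ok <- tryCatch({
      suppressWarnings(utils::download.file(u, dest, quiet = TRUE,
                                            method = "libcurl"))
      file.exists(dest) && file.size(dest) > 1000
    }, error = function(e) FALSE)
    if (isTRUE(ok)) return(dest)
    unlink(dest)
  }
  warning("structure ", id, " unavailable: not cached in ", cache_dir,
          " and download failed (offline?)")
  NULL
}

#' Locate or download a reference proteome FASTA
#'
#' Looks for `file_name` in `cache_dir`, then attempts a UniProt download of
#' the human reference proteome. Returns `NULL` with a warning when
#' unavailable.
#'
#' @param file_name Expected FASTA file name in the cache.
#' @param cache_dir Directory searched first and used to store downloads.
#' @return Path to a FASTA file, or `NULL` if unavailable.
#' @export
fetch_proteome_fasta <- function(file_name = "human_proteome.fasta",
                                 cache_dir = tools::R_user_dir("ankgroove",
                                                               "cache")) {
  p <- file.path(cache_dir, file_name)
  if (file.exists(p)) return(p)
  gz <- paste0(p, ".gz")
  if (file.exists(gz)) return(gz)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  url <- paste0("https://rest.uniprot.org/uniprotkb/stream?",
                "query=proteome:UP000005640&format=fasta&compressed=true")
  ok <- tryCatch({
    suppressWarnings(utils::download.file(url, gz, quiet = TRUE,
                                          method = "libcurl"))
    file.exists(gz) && file.size(gz) > 1e5
  }, error = function(e) FALSE)
  if (isTRUE(ok)) return(gz)
  unlink(gz)
  warning("reference proteome unavailable: not cached in ", cache_dir,
          " and download failed (offline?)")
  NULL
}
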