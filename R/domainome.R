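#' Load per-genome protein-domain annotations
#'
#' Two dialects:
#' \describe{
#'   \item{interproscan_tsv}{the standard InterProScan output (11-15
#'     tab-separated columns, no header); the InterPro accession is column
#'     12. Rows with an empty or `"-"` accession (signature hits with no
#'     InterPro mapping) are skipped and counted.}
#'   \item{simple_tsv}{three columns `genome_id`, `gene_id`, `domain_id`
#'     with a header row (the synthetic-generator format).}
#' }
#' Domain presence is genome-level boolean: the result is the set of
#' distinct accessions observed in at least one protein; copy number is
#' ignored.
#'
#' @param path TSV file path.
#' @param dialect `"simple_tsv"` (default) or `"interproscan_tsv"`.
#' @param genome_id genome identifier; for simple_tsv defaults to the value
#'   in the file, for interproscan_tsv to the file name.
#' @param group `"anaerobe"` or `"aerobe"` panel assignment.
#' @param strict error (with line number) on malformed rows instead of
#'   skip-and-count.
#' @return an object of class `genome_domain_set`: list with `genome_id`,
#'   `group`, `domains` (sorted character vector), `gene_count`,
#'   `n_skipped`.
#' @export
load_domain_annotations <- function(path,
                                    dialect = c("simple_tsv",
                                                "interproscan_tsv"),
                                    genome_id = NULL,
                                    group = c("anaerobe", "aerobe"),
                                    strict = FALSE) {
  dialect <- match.arg(dialect)
  group <- match.arg(group)
  if (dialect == "simple_tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    need <- c("genome_id", "gene_id", "domain_id")
    if (!all(need %in% names(df))) {
      stop("simple_tsv '", path, "' must have columns ",
           paste(need, collapse = ", "))
    }
    if (is.null(genome_id)) genome_id <- df$genome_id[1]
    domains <- df$domain_id
    genes <- unique(df$gene_id)
    n_skipped <- 0L
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nfld <- lengths(fields)
    bad <- which(nfld < 11L)
    if (length(bad) && strict) {
      stop("malformed InterProScan row (fewer than 11 columns) at line ",
           bad[1], " of '", path, "'")
    }
    acc <- vapply(fields, function(f) {
      if (length(f) >= 12L) f[[12]] else ""
    }, character(1))
    keep <- !(seq_along(fields) %in% bad) & nzchar(acc) & acc != "-"
    domains <- acc[keep]
    genes <- unique(vapply(fields, `[[`, character(1), 1L))
    n_skipped <- sum(!keep)
    if (is.null(genome_id)) {
      genome_id <- tools::file_path_sans_ext(basename(path))
    }
  }
  domains <- sort(unique(domains))
  if (!length(domains)) {
    stop("no domain accessions found in '", path, "'")
  }
  bad_acc <- domains[!grepl("^[A-Za-z]+[0-9]+$", domains)]
  if (length(bad_acc)) {
    stop("accession(s) not matching letter-prefix + digits in '", path,
         "': ", paste(utils::head(bad_acc, 3), collapse = ", "))
  }
  structure(list(genome_id = genome_id, group = group, domains = domains,
                 gene_count = length(genes), n_skipped = n_skipped),
            class = "genome_domain_set")
}

#' Core domainome of a genome group
#'
#' The set of domain accessions present in every genome of the group
#' (intersection over all member sets).
#'
#' @param group non-empty list of `genome_domain_set`s.
#' @return sorted character vector of accessions.
#' @export
core_domains <- function(group) {
  if (!length(group)) stop("core_domains: empty genome group")
  sort(Reduce(intersect, lapply(group, `[[`, "domains")))
}

#' Group-exclusive core domains
#'
#' Domains common to all target genomes and absent from every background
#' genome: `core_domains(target)` minus the union of all background sets.
#' The result is by construction a subset of the target core and disjoint
#' from every background set (asserted).
#'
#' @param target,background non-empty lists of `genome_domain_set`s.
#' @return sorted character vector of accessions.
#' @export
exclusive_core <- function(target, background) {
  if (!length(background)) stop("exclusive_core: empty background group")
  core <- core_domains(target)
  out <- sort(setdiff(core, unique(unlist(lapply(background, `[[`,
                                                 "domains")))))
  stopifnot(all(out %in% core),
            !any(vapply(background,
                        function(g) any(out %in% g$domains), logical(1))))
  out
}

#' Default functional category map
#'
#' Maps the shortlist accessions with known roles: acetate kinase
#' (IPR000890) and the two ribonucleotide-triphosphate-reductase domains
#' (IPR012833, IPR012840) to `atp_generation`; siderophore-transport,
#' pilus-assembly and iron-sulfur-cluster domains to `other`. Everything
#' else defaults to `unknown_function` at categorization time; a full map
#' can be supplied by the user.
#'
#' @return named character vector accession -> category.
#' @export
default_category_map <- function() {
  c(IPR000890 = "atp_generation", IPR012833 = "atp_generation",
    IPR012840 = "atp_generation",
    IPR003538 = "other", IPR008707 = "other", IPR013362 = "other",
    IPR013374 = "other", IPR025746 = "other", IPR007202 = "other",
    IPR018298 = "other")
}

#' Categorize a domain shortlist
#'
#' Assigns every accession exactly one of the three categories
#' `atp_generation`, `unknown_function`, `other`. Accessions absent from
#' the map default to `unknown_function`.
#'
#' @param domains character vector of accessions.
#' @param category_map named character vector accession -> category;
#'   default [default_category_map()].
#' @return list with `counts` (named integer vector over the three
#'   categories), `total`, `assignments` (data.frame accession,
#'   category), `n_unmapped`.
#' @export
categorize_domains <- function(domains, category_map =
                                 default_category_map()) {
  allowed <- c("atp_generation", "unknown_function", "other")
  if (length(category_map) && !all(category_map %in% allowed)) {
    stop("category map contains categories outside {",
         paste(allowed, collapse = ", "), "}")
  }
  domains <- sort(unique(domains))
  cat <- unname(category_map[domains])
  unmapped <- is.na(cat)
  cat[unmapped] <- "unknown_function"
  counts <- vapply(allowed, function(a) sum(cat == a), integer(1))
  stopifnot(sum(counts) == length(domains))
  list(counts = counts, total = length(domains),
       assignments = data.frame(accession = domains, category = cat,
                                stringsAsFactors = FALSE),
       n_unmapped = sum(unmapped))
}

#' Presence/absence matrix of a genome panel
#'
#' @param sets list of `genome_domain_set`s.
#' @return logical matrix, genomes (rows) x domains (columns, sorted).
#' @export
presence_absence_matrix <- function(sets) {
  doms <- sort(unique(unlist(lapply(sets, `[[`, "domains"))))
  gids <- vapply(sets, `[[`, character(1), "genome_id")
  m <- matrix(FALSE, length(sets), length(doms),
              dimnames = list(gids, doms))
  for (i in seq_along(sets)) m[i, sets[[i]]$domains] <- TRUE
  m
}

#' Write a shortlist report as TSV
#'
#' One row per shortlisted accession: its category and per-genome presence
#' flags.
#'
#' @param shortlist character vector of accessions.
#' @param sets list of `genome_domain_set`s (all panels).
#' @param category_map accession -> category map.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shortlist_report <- function(shortlist, sets, path,
                                   category_map = default_category_map()) {
  cats <- categorize_domains(shortlist, category_map)$assignments
  pres <- lapply(sets, function(g) {
    as.integer(cats$accession %in% g$domains)
  })
  names(pres) <- vapply(sets, `[[`, character(1), "genome_id")
  df <- cbind(cats, as.data.frame(pres, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
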