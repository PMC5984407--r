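# File formats.
#
# Genotype dialect: plain CSV with one row per individual.  Mandatory
# columns `id` and `site`; every other column is a locus whose cells hold
# slash-separated allele sizes in bp ("133/177/181").  An empty cell is
# missing data.  Fragment-size binning is assumed done upstream, so sizes
# are integers.  Loci are declared in a YAML config (see
# [readLocusConfig()]); a genotype column absent from the config is an
# error.

#' Read a locus-definition config
#'
#' YAML with one entry per locus:
#' \preformatted{
#' AmaD42:
#'   motif: 4
#'   j_range: [133, 193]
#'   l_range: [209, 261]
#' AjeD94:
#'   motif: 4
#'   rule: NON_DISCRIMINATING
#' }
#' `rule` is derived from the ranges when omitted (both ranges ->
#' SPLIT_BY_RANGE, one -> J_ONLY / L_ONLY, none -> NON_DISCRIMINATING).
#'
#' @param path YAML file path.
#' @return locus table as from [locusTable()].
#' @export
readLocusConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) stop("empty locus config: ", path)
  parseRange <- function(x) {
    if (is.null(x)) c(NA_real_, NA_real_) else {
      if (length(x) != 2 || x[1] > x[2])
        stop("malformed range in locus config: ", paste(x, collapse = ","))
      as.numeric(x)
    }
  }
  jr <- t(vapply(cfg, function(e) parseRange(e$j_range), numeric(2)))
  lr <- t(vapply(cfg, function(e) parseRange(e$l_range), numeric(2)))
  motif <- vapply(cfg, function(e) {
    if (is.null(e$motif)) stop("locus config entry lacks motif length")
    as.integer(e$motif)
  }, integer(1))
  rule <- vapply(cfg, function(e)
    if (is.null(e$rule)) NA_character_ else e$rule, character(1))
  tab <- locusTable(names(cfg), motif, jr, lr)
  tab$rule[!is.na(rule)] <- rule[!is.na(rule)]
  tab
}

parseAlleleCell <- function(cell, row, col) {
  cell <- trimws(cell)
  if (is.na(cell) || cell == "" || toupper(cell) == "NA") return(integer(0))
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || any(vals != round(vals)))
    stop(sprintf("non-numeric allele '%s' at row %s, column %s",
                 cell, row, col))
  sort(unique(as.integer(vals)))
}

#' Read a genotype CSV into an MsatDataset
#'
#' @param path genotype CSV (see the dialect described above).
#' @param locus_config path to a YAML locus config, or a locus table
#'   data.frame as returned by [readLocusConfig()]/[locusTable()].
#' @param sites optional data.frame (site, lat, lon); defaults to the
#'   sites seen in the file, without coordinates.
#' @return an [MsatDataset-class].
#' @export
readGenotypeTable <- function(path, locus_config, sites = NULL) {
  loci <- if (is.character(locus_config)) readLocusConfig(locus_config)
          else locus_config
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("id", "site") %in% names(raw)))
    stop("genotype table needs 'id' and 'site' columns")
  locCols <- setdiff(names(raw), c("id", "site", "mtdna_unisexual"))
  unknown <- setdiff(locCols, loci$name)
  if (length(unknown))
    stop("unknown locus column in genotype table: ",
         paste(unknown, collapse = ", "))
  loci <- loci[loci$name %in% locCols, , drop = FALSE]
  rownames(loci) <- NULL
  if (anyDuplicated(raw$id))
    stop("duplicate individual id: ", raw$id[duplicated(raw$id)][1])
  g <- matrix(vector("list", nrow(raw) * nrow(loci)),
              nrow = nrow(raw), ncol = nrow(loci))
  for (j in seq_len(nrow(loci))) {
    col <- raw[[loci$name[j]]]
    for (i in seq_len(nrow(raw)))
      g[[i, j]] <- parseAlleleCell(col[i], raw$id[i], loci$name[j])
  }
  ind <- data.frame(id = raw$id, site = raw$site, stringsAsFactors = FALSE)
  if ("mtdna_unisexual" %in% names(raw))
    ind$mtdna_unisexual <- as.logical(raw$mtdna_unisexual)
  ds <- newMsatDataset(g, loci, ind, sites)
  missFrac <- colMeans(matrix(lengths(g) == 0, nrow = nrow(raw)))
  if (any(missFrac > 0.5))
    warning("locus missing in >50% of individuals: ",
            paste(loci$name[missFrac > 0.5], collapse = ", "))
  ds
}

#' Write an MsatDataset back to genotype CSV
#'
#' Round-trips with [readGenotypeTable()]: write-then-read reproduces the
#' genotypes, ids and sites exactly.
#'
#' @param dataset an [MsatDataset-class].
#' @param path output CSV path.
#' @export
writeGenotypeTable <- function(dataset, path) {
  g <- dataset@genotypes
  cells <- apply(g, c(1, 2), function(a) paste(a[[1]], collapse = "/"))
  out <- data.frame(id = dataset@individuals$id,
                    site = dataset@individuals$site,
                    cells, check.names = FALSE)
  colnames(out) <- c("id", "site", dataset@loci$name)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary AFLP presence/absence CSV
#'
#' CSV with an `id` column and one 0/1 column per band.
#'
#' @param path CSV path.
#' @return an [AflpMatrix-class].
#' @export
readAflpMatrix <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("AFLP file must have an id column and at least one band")
  if (!"id" %in% names(raw)) stop("AFLP file needs an 'id' column")
  m <- as.matrix(raw[, setdiff(names(raw), "id"), drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1)))
    stop("AFLP cells must all be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- raw$id
  new("AflpMatrix", presence = m)
}

#' Write an AFLP matrix to CSV
#' @param aflp an [AflpMatrix-class].
#' @param path output path.
#' @export
writeAflpMatrix <- function(aflp, path) {
  m <- aflp@presence
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tree in newick format
#'
#' Internal-node support values (when present as `node.label`) are written
#' as internal node labels, the convention FigTree and most viewers read.
#'
#' @param tree an ape `phylo` object.
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path newick file.
#' @return ape `phylo`.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' Write / read a labeled symmetric matrix as CSV
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param path CSV path.
#' @export
writeMatrixCSV <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMatrixCSV
#' @export
readMatrixCSV <- function(path) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(raw)
}

#' Export diploid (LL) individuals in Genepop format
#'
#' Only fully diploid individuals can be represented; alleles are coded as
#' three-digit sizes.  Useful for cross-checking LL allele frequencies in
#' classic diploid software.
#'
#' @param dataset an [MsatDataset-class] with biotypes called.
#' @param path output path.
#' @param title header line.
#' @export
writeGenepop <- function(dataset, path, title = "kleptopop LL export") {
  ind <- dataset@individuals
  keep <- ind$biotype == "LL"
  if (!any(keep)) stop("no LL individuals to export")
  loci <- dataset@loci$name
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (s in unique(ind$site[keep])) {
    writeLines("POP", con)
    for (i in which(keep & ind$site == s)) {
      codes <- vapply(seq_along(loci), function(j) {
        a <- dataset@genotypes[[i, j]]
        if (length(a) == 0) return("000000")
        if (length(a) == 1) a <- c(a, a)
        if (length(a) > 2)
          stop("non-diploid genotype in LL export: ", ind$id[i])
        paste(sprintf("%03d", a), collapse = "")
      }, character(1))
      writeLines(sprintf("%s , %s", ind$id[i], paste(codes, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
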