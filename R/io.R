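#' Write / read an ALD curve set as TSV
#'
#' The exchange format is a tab-separated table with columns `distance`
#' (Morgans), `value`, `n_pairs`, `label` ("full" or "drop_chrom:<c>"),
#' preceded by comment header lines `# m1=<x>` and `# N=<n>`.  Values
#' round-trip at 12 significant digits.
#'
#' @param x an \linkS4class{LDCurveSet}.
#' @param path file path.
#' @param extraHeader optional extra comment line(s) (e.g. provenance).
#' @return `writeCurveSet`: the path, invisibly. `readCurveSet`: an
#'   \linkS4class{LDCurveSet}.
#' @export
writeCurveSet <- function(x, path, extraHeader = NULL) {
  stopifnot(is(x, "LDCurveSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# m1=%.12g", x@m1),
               sprintf("# N=%d", length(x@jackknives)),
               extraHeader), con)
  oneCurve <- function(cv)
    data.frame(distance = sprintf("%.12g", cv@d),
               value = sprintf("%.12g", cv@z),
               n_pairs = sprintf("%.12g", cv@nPairs),
               label = cv@label)
  tab <- do.call(rbind, c(list(oneCurve(x@full)),
                          lapply(x@jackknives, oneCurve)))
  writeLines(paste(c("distance", "value", "n_pairs", "label"),
                   collapse = "\t"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCurveSet
#' @export
readCurveSet <- function(path) {
  hdr <- readLines(path, n = 50)
  hdr <- hdr[startsWith(hdr, "#")]
  getNum <- function(key) {
    ln <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (length(ln) == 0) stop(sprintf("curve file lacks '# %s=' header", key))
    as.numeric(sub(sprintf("^#\\s*%s=", key), "", ln[1]))
  }
  m1 <- getNum("m1"); N <- getNum("N")
  if (!(m1 > 0 && m1 < 1))
    stop(sprintf("m1=%g outside (0,1) in curve file header", m1))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  mk <- function(sub, label) {
    bad <- which(diff(sub$distance) <= 0)
    if (length(bad))
      stop(sprintf("non-monotone distance in curve '%s' at row %d",
                   label, bad[1] + 1))
    LDCurve(sub$distance, sub$value, sub$n_pairs, label)
  }
  labs <- unique(tab$label)
  if (!"full" %in% labs) stop("curve file lacks the 'full' curve")
  jlabs <- setdiff(labs, "full")
  if (length(jlabs) != N)
    stop(sprintf("header says N=%d but file has %d jackknife curves",
                 N, length(jlabs)))
  full <- mk(tab[tab$label == "full", ], "full")
  jack <- lapply(jlabs, function(lb) mk(tab[tab$label == lb, ], lb))
  names(jack) <- sub("^drop_chrom:", "", jlabs)
  LDCurveSet(full, jack, m1)
}

# ---- panel readers ---------------------------------------------------------

readMapFile <- function(path, unit = c("morgan", "cm")) {
  unit <- match.arg(unit)
  map <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("map file needs columns: chrom, id, gdist, bp")
  names(map)[1:4] <- c("chrom", "id", "gpos", "bp")
  map$chrom <- as.character(map$chrom)
  if (unit == "cm") map$gpos <- map$gpos / 100
  map
}

readPlainHaps <- function(path, map, popLabel) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != nrow(map))
    stop(sprintf("%s: %d haplotype columns but %d map sites",
                 path, ncol(m), nrow(map)))
  m[m == 9] <- NA
  colnames(m) <- map$id
  list(alleles = m, chrom = map$chrom, gpos = map$gpos, ploidy = 1L,
       id = map$id, popLabel = popLabel)
}

readEigenstrat <- function(prefix, popLabel, unit = "morgan") {
  snp <- utils::read.table(paste0(prefix, ".snp"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(snp)[1:4] <- c("id", "chrom", "gpos", "bp")
  if (unit == "cm") snp$gpos <- snp$gpos / 100
  lines <- readLines(paste0(prefix, ".geno"))
  if (length(lines) != nrow(snp))
    stop(sprintf("%s.geno has %d rows but .snp has %d sites",
                 prefix, length(lines), nrow(snp)))
  g <- vapply(strsplit(lines, ""), function(ch) as.numeric(ch),
              numeric(nchar(lines[1])))
  g[g == 9] <- NA                     # g: individuals x sites
  colnames(g) <- snp$id
  list(alleles = g, chrom = as.character(snp$chrom), gpos = snp$gpos,
       ploidy = 2L, id = snp$id, popLabel = popLabel)
}

readVcfPanel <- function(path, map, popLabel, asGenotypes = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  key <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = ":")
  mkey <- paste(map$chrom, map$bp, sep = ":")
  hit <- match(key, mkey)
  if (anyNA(hit)) {
    message(sprintf("%s: dropping %d site(s) lacking a genetic map entry",
                    path, sum(is.na(hit))))
    gt <- gt[!is.na(hit), , drop = FALSE]
    key <- key[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  if (nrow(gt) == 0) stop("no VCF site has a genetic map entry")
  if (asGenotypes) {
    dose <- apply(gt, 2, function(s) {
      a <- strsplit(s, "[|/]")
      vapply(a, function(x) sum(as.numeric(x)), numeric(1))
    })
    alleles <- matrix(dose, ncol = ncol(gt))
    alleles <- t(alleles)             # individuals x sites
    ploidy <- 2L
  } else {
    if (any(grepl("/", gt)))
      stop("unphased genotypes ('/' separator) cannot be read as haplotypes; use asGenotypes = TRUE")
    hapList <- apply(gt, 2, function(s) {
      a <- do.call(rbind, strsplit(s, "|", fixed = TRUE))
      matrix(as.numeric(a), ncol = 2)
    }, simplify = FALSE)
    alleles <- t(do.call(cbind, lapply(hapList, function(h) h)))
    ploidy <- 1L
  }
  list(alleles = alleles, chrom = map$chrom[hit], gpos = map$gpos[hit],
       ploidy = ploidy, id = map$id[hit], popLabel = popLabel)
}

#' Read the three panels (admixed + two sources)
#'
#' Reads and aligns the admixed and source panels from one of three
#' formats.  Panels must cover the same site set (an error names the first
#' divergent site otherwise); differing on-disk site orders are aligned.
#' Genetic positions are canonicalized to Morgans (`unit = "cm"` converts
#' centiMorgan inputs at read time).
#'
#' @param admixed,source1,source2 file paths: for "plain_haps" the
#'   haplotype matrix files; for "vcf" the VCF files; for "eigenstrat" the
#'   path prefixes of .geno/.snp file pairs.
#' @param format input format.
#' @param map path to a 4-column map file (chrom, id, genetic distance,
#'   bp) required for plain_haps and vcf.
#' @param unit genetic-distance unit in the map / .snp file.
#' @param asGenotypes read VCF as diploid dosages instead of phased
#'   haplotypes (allele-frequency computations never require phase).
#' @return named list of three aligned \linkS4class{HaplotypePanel}s.
#' @export
readPanels <- function(admixed, source1, source2,
                       format = c("plain_haps", "vcf", "eigenstrat"),
                       map = NULL, unit = c("morgan", "cm"),
                       asGenotypes = FALSE) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  paths <- list(admixed = admixed, source1 = source1, source2 = source2)
  raw <- switch(format,
    plain_haps = {
      if (is.null(map)) stop("plain_haps format requires a map file")
      mp <- readMapFile(map, unit)
      lapply(names(paths), function(nm) readPlainHaps(paths[[nm]], mp, nm))
    },
    vcf = {
      if (is.null(map)) stop("vcf format requires a map file for genetic positions")
      mp <- readMapFile(map, unit)
      lapply(names(paths), function(nm)
        readVcfPanel(paths[[nm]], mp, nm, asGenotypes))
    },
    eigenstrat = lapply(names(paths), function(nm)
      readEigenstrat(paths[[nm]], nm, unit)))
  names(raw) <- names(paths)

  ids <- lapply(raw, `[[`, "id")
  common <- Reduce(intersect, ids)
  for (nm in names(raw)) {
    extra <- setdiff(ids[[nm]], common)
    if (length(extra))
      stop(sprintf("mismatched site sets: site '%s' present in '%s' but not in all panels",
                   extra[1], nm))
  }
  lapply(raw, function(p) {
    o <- match(common, p$id)
    HaplotypePanel(p$alleles[, o, drop = FALSE], p$chrom[o], p$gpos[o],
                   p$ploidy, p$popLabel)
  })
}

#' Write a panel set as plain haplotype matrices plus a map file
#'
#' @param panels named list (admixed, source1, source2) of
#'   \linkS4class{HaplotypePanel}s on a common site set.
#' @param dir output directory.
#' @param extraHeader optional comment line(s) prepended to the map file.
#' @return (invisibly) the written paths.
#' @export
writePanelSet <- function(panels, dir, extraHeader = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p0 <- panels[[1]]
  map <- data.frame(chrom = p0@chrom,
                    id = sprintf("site%d", seq_len(nSites(p0))),
                    gpos = sprintf("%.12g", p0@gpos),
                    bp = seq_len(nSites(p0)))
  mapPath <- file.path(dir, "sites.map")
  con <- file(mapPath, "w")
  if (!is.null(extraHeader)) writeLines(extraHeader, con)
  utils::write.table(map, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  paths <- c(map = mapPath)
  for (nm in names(panels)) {
    a <- panels[[nm]]@alleles
    a[is.na(a)] <- 9
    path <- file.path(dir, paste0(nm, ".haps"))
    utils::write.table(a, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Write a selection report as JSON
#'
#' Mirrors the per-model diagnostics layout (model, end, start, msE,
#' quasi-F, best-fit marker) plus the adjusted p-value table and the
#' selected model set.
#'
#' @param report a \linkS4class{SelectionReport}.
#' @param path output path.
#' @param provenance optional named list stored under `provenance`.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path, provenance = NULL) {
  stopifnot(is(report, "SelectionReport"))
  out <- list(
    best_models = report@bestSet,
    undetermined = report@undetermined,
    alpha = report@alpha,
    table = report@diagnostics,
    adjusted_p = as.data.frame(as.table(report@adjP),
                               stringsAsFactors = FALSE),
    pseudo_log_msE = unclass(report@pseudo))
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}
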