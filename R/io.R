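#' Construct a ReciprocalCross from in-memory pieces
#'
#' @param genotypes Integer matrix, markers x individuals, codes 1 = `11`,
#'   2 = `12`, 3 = `22`, `NA` missing.  Row names are marker names.
#' @param map `data.frame` with columns `marker`, `chromosome`,
#'   `position_cM`; markers must cover the rows of `genotypes`.
#' @param family Integer vector (1-4) giving each individual's mating type,
#'   in the order of [iqtlMatingTypes()].
#' @param phenotype Numeric vector of trait values, one per individual.
#' @param maternal,paternal Optional integer matrices (same shape as
#'   `genotypes`, values 1, 2 or `NA`) giving the marker allele transmitted
#'   by the maternal and paternal gamete — phase-known transmission, which
#'   makes the two heterozygous QTL configurations distinguishable (see
#'   [orderedConfigPriors()]).
#' @param metadata Optional list stored in `metadata()` (e.g. simulation
#'   truth).
#' @return A [ReciprocalCross-class] object.
#' @export
makeReciprocalCross <- function(genotypes, map, family, phenotype,
                                maternal = NULL, paternal = NULL,
                                metadata = list()) {
  map <- validateMap(map)
  if (is.null(rownames(genotypes)))
    stop("'genotypes' must have marker row names")
  missing <- setdiff(rownames(genotypes), map$marker)
  if (length(missing))
    stop("markers absent from the map: ", paste(missing, collapse = ", "))
  map <- map[match(rownames(genotypes), map$marker), , drop = FALSE]
  ## keep map order: sort rows by chromosome then position
  ord <- order(match(map$chromosome, unique(map$chromosome)), map$position_cM)
  genotypes <- genotypes[ord, , drop = FALSE]
  map <- map[ord, , drop = FALSE]
  assays <- list(genotype = genotypes)
  if (!is.null(maternal) || !is.null(paternal)) {
    if (is.null(maternal) || is.null(paternal) ||
        !all(dim(maternal) == dim(genotypes)) ||
        !all(dim(paternal) == dim(genotypes)))
      stop("'maternal' and 'paternal' must both be given, same shape as 'genotypes'")
    maternal <- maternal[ord, , drop = FALSE]
    paternal <- paternal[ord, , drop = FALSE]
    reco <- maternal + paternal - 1L
    if (any(!is.na(reco) & !is.na(genotypes) & reco != genotypes))
      stop("phase assays are inconsistent with the unordered genotypes")
    assays$maternal <- maternal
    assays$paternal <- paternal
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(chromosome = map$chromosome,
                                   position = map$position_cM,
                                   row.names = map$marker),
    colData = S4Vectors::DataFrame(family = as.integer(family),
                                   phenotype = as.numeric(phenotype)),
    metadata = metadata)
  methods::new("ReciprocalCross", se)
}

validateMap <- function(map) {
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% colnames(map)))
    stop("map must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker))
    stop("duplicate marker names in map: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  if (!is.numeric(map$position_cM) || any(!is.finite(map$position_cM)))
    stop("map positions must be finite numbers")
  bad <- vapply(split(map$position_cM, map$chromosome),
                function(p) any(diff(sort(p)) <= 0) || is.unsorted(p),
                logical(1L))
  if (any(bad))
    stop("marker positions must be strictly increasing within chromosome(s): ",
         paste(names(bad)[bad], collapse = ", "))
  map$marker <- as.character(map$marker)
  map$chromosome <- as.character(map$chromosome)
  map
}

#' Read and write linkage maps and cross files
#'
#' @description
#' The on-disk dialect is plain CSV.  A map file has header
#' `marker,chromosome,position_cM`; positions must be strictly increasing
#' within each chromosome.  A cross file has header
#' `family,individual,phenotype,<marker1>,<marker2>,...` with genotypes coded
#' `11`, `12`, `22` or `NA` and `family` coded 1-4 in the order of
#' [iqtlMatingTypes()].  For the mouse survival example that motivates the
#' design, allele 1 corresponds to the sensitive C57BL/6J (B) allele and
#' allele 2 to the resistant 129X1/SvJ (S) allele.
#'
#' When the parental origin of marker alleles has been traced through the
#' pedigree, genotypes may instead be written phase-known as
#' `maternal|paternal` allele pairs (`1|1`, `1|2`, `2|1`, `2|2`, with `?`
#' for a missing allele, e.g. `1|?`); [readCrossFile()] detects this dialect
#' per cell and stores the phase assays used by [orderedConfigPriors()].
#' `writeCrossFile(ordered = TRUE)` writes it when the cross carries phase.
#'
#' @param path File path.
#' @param map A map `data.frame` (as returned by [readMarkerMap()]) used to
#'   validate and order the cross's markers.
#' @param cross A [ReciprocalCross-class] object.
#' @param ordered Write phase-known `maternal|paternal` genotype codes
#'   (requires the phase assays).
#' @return `readMarkerMap()`: a validated map `data.frame`;
#'   `readCrossFile()`: a [ReciprocalCross-class]; the writers return the
#'   path invisibly.
#' @export
readMarkerMap <- function(path) {
  validateMap(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readMarkerMap
#' @export
readCrossFile <- function(path, map) {
  map <- validateMap(map)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("family", "individual", "phenotype")
  if (!all(need %in% colnames(df)))
    stop("cross file must have columns ", paste(need, collapse = ", "))
  markers <- setdiff(colnames(df), need)
  unknown <- setdiff(markers, map$marker)
  if (length(unknown))
    stop("markers not on the map: ", paste(unknown, collapse = ", "))
  fam <- suppressWarnings(as.integer(df$family))
  if (any(is.na(fam) | !fam %in% 1:4))
    stop("family must be coded 1-4; offending row(s): ",
         paste(which(is.na(fam) | !fam %in% 1:4), collapse = ", "))
  phe <- suppressWarnings(as.numeric(df$phenotype))
  if (any(is.na(phe)))
    stop("non-numeric phenotype in row(s): ",
         paste(which(is.na(phe)), collapse = ", "))
  dn <- list(markers, df$individual)
  geno <- matrix(NA_integer_, length(markers), nrow(df), dimnames = dn)
  matA <- matrix(NA_integer_, length(markers), nrow(df), dimnames = dn)
  patA <- matrix(NA_integer_, length(markers), nrow(df), dimnames = dn)
  anyPhase <- FALSE
  codes <- c("11" = 1L, "12" = 2L, "22" = 3L, "21" = 2L)
  allele <- c("1" = 1L, "2" = 2L, "?" = NA_integer_)
  for (m in markers) {
    v <- df[[m]]
    miss <- is.na(v) | v == "NA"
    phased <- !miss & grepl("|", v, fixed = TRUE)
    plain <- !miss & !phased
    bad <- plain & !v %in% names(codes)
    if (!any(bad) && any(phased)) {
      parts <- strsplit(v[phased], "|", fixed = TRUE)
      badp <- lengths(parts) != 2L |
        !vapply(parts, function(p) all(p %in% names(allele)), logical(1L))
      if (any(badp)) bad[which(phased)[badp]] <- TRUE
    }
    if (any(bad))
      stop("unknown genotype code '", v[which(bad)[1L]], "' at row ",
           which(bad)[1L], ", marker ", m)
    geno[m, plain] <- codes[v[plain]]
    if (any(phased)) {
      anyPhase <- TRUE
      parts <- strsplit(v[phased], "|", fixed = TRUE)
      matA[m, phased] <- allele[vapply(parts, `[`, "", 1L)]
      patA[m, phased] <- allele[vapply(parts, `[`, "", 2L)]
      both <- matA[m, ] + patA[m, ] - 1L
      geno[m, phased] <- both[phased]
    }
  }
  if (anyPhase) makeReciprocalCross(geno, map, fam, phe,
                                    maternal = matA, paternal = patA)
  else makeReciprocalCross(geno, map, fam, phe)
}

#' @rdname readMarkerMap
#' @export
writeMarkerMap <- function(cross, path) {
  rd <- SummarizedExperiment::rowData(cross)
  utils::write.csv(data.frame(marker = rownames(cross),
                              chromosome = rd$chromosome,
                              position_cM = rd$position),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readMarkerMap
#' @export
writeCrossFile <- function(cross, path, ordered = FALSE) {
  g <- SummarizedExperiment::assay(cross, "genotype")
  if (ordered) {
    an <- SummarizedExperiment::assayNames(cross)
    if (!all(c("maternal", "paternal") %in% an))
      stop("'ordered = TRUE' requires the 'maternal' and 'paternal' assays")
    toChar <- function(x) ifelse(is.na(x), "?", as.character(x))
    ma <- SummarizedExperiment::assay(cross, "maternal")
    pa <- SummarizedExperiment::assay(cross, "paternal")
    gm <- matrix(paste0(toChar(ma), "|", toChar(pa)), nrow(g), ncol(g))
    gm[is.na(ma) & is.na(pa)] <- "NA"
  } else {
    lab <- c("11", "12", "22")[g]
    gm <- matrix(ifelse(is.na(lab), "NA", lab), nrow(g), ncol(g))
  }
  cd <- SummarizedExperiment::colData(cross)
  ids <- colnames(cross)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(cross)))
  df <- data.frame(family = cd$family, individual = ids,
                   phenotype = cd$phenotype,
                   t(gm), check.names = FALSE)
  colnames(df)[-(1:3)] <- rownames(g)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Map data.frame of a cross object.
crossMap <- function(cross) {
  rd <- SummarizedExperiment::rowData(cross)
  data.frame(marker = rownames(cross), chromosome = rd$chromosome,
             position_cM = rd$position, stringsAsFactors = FALSE)
}

#' Write scan results and a run manifest
#'
#' Writes the LR profile as TSV (`profile.tsv`), called peaks with their
#' imprinting-test p-values as JSON (`peaks.json`), and a `manifest.json`
#' recording the configuration, seed and package version, into `dir`.
#' Outputs are deterministic given the same scan object and manifest.
#'
#' @param scan An [IQTLScan-class] object.
#' @param dir Output directory (created if needed).
#' @param config Named list recorded in the manifest (include the seed).
#' @return Invisibly, the paths written.
#' @export
writeScanResults <- function(scan, dir, config = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(profile = file.path(dir, "profile.tsv"),
             peaks = file.path(dir, "peaks.json"),
             manifest = file.path(dir, "manifest.json"))
  prof <- scanProfile(scan)
  utils::write.table(prof, paths["profile"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(threshold = scan@threshold, alpha = scan@alpha, peaks = scan@peaks),
    paths["peaks"], auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- c(config,
                list(package = "iqtlmap",
                     version = as.character(utils::packageVersion("iqtlmap"))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Serialise a fit as JSON
#'
#' Writes the effect estimates (keyed by the 16 effect names), the
#' constrained set, residual variance, log-likelihood and convergence flag.
#'
#' @param fit An [IQTLFit-class] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFit <- function(fit, path) {
  jsonlite::write_json(
    list(effects = as.list(effectEstimates(fit)),
         constrained = constrainedEffects(fit),
         sigma2 = residualVariance(fit),
         logLik = fit@logLik,
         converged = fit@converged,
         iterations = fit@nIter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
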