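#' @keywords internal
"_PACKAGE"

## Closed vocabulary of higher taxa recorded in the field survey. Phenotypes
## (operational taxonomic units distinguished visually) are always assigned to
## one of these nine groups; anything else is a data-entry error.
INCIDIV_TAXA <- c(
  "Ascidiacea", "Bryozoa", "Cnidaria", "Entoprocta", "Foraminifera",
  "Mollusca (Bivalvia)", "Polychaeta (Sedentaria)", "Rotifera", "Porifera"
)

INCIDIV_HABITATS <- c("PC_mat", "PO_leaves", "PO_rhizomes", "PO_holobiont")

#' Nine-taxon vocabulary for sessile invertebrate phenotypes
#'
#' @return Character vector of the nine higher-taxon codes accepted by
#'   [read_count_table()].
#' @export
incidiv_taxa <- function() INCIDIV_TAXA

#' Construct a phenotype-by-sample count table
#'
#' The central abundance container: an integer matrix of phenotype counts per
#' sampling unit, together with the per-sample 3D substrate surface area and
#' the habitat's surface-enlargement factor needed to express abundances per
#' habitat square metre and per seafloor square metre.
#'
#' @param counts integer matrix, phenotypes in rows, samples in columns;
#'   dimnames required.
#' @param sample_area_3d numeric vector of per-sample 3D substrate surface
#'   area in m^2 (recycled if length 1), or `NULL` if unknown.
#' @param enlargement_factor dimensionless enlargement factor (EF >= 1)
#'   converting habitat-m^2 densities to seafloor-m^2 densities; may be a
#'   single value or per-sample vector.
#' @param frame_area planar area of the sampling frame in m^2 (0.09 for algal
#'   mats, 0.16 for rhizome density frames, 0.04 for hard bottom).
#' @param habitat habitat label, one of `PC_mat`, `PO_leaves`, `PO_rhizomes`,
#'   `PO_holobiont`.
#' @param taxon optional named character vector mapping phenotype ids to the
#'   nine-taxon vocabulary.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_area_3d = NULL, enlargement_factor = NA_real_,
                        frame_area = NA_real_, habitat = NA_character_, taxon = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("p", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (anyDuplicated(rownames(counts))) stop("phenotype ids must be unique")
  if (!is.null(sample_area_3d)) {
    sample_area_3d <- rep_len(as.numeric(sample_area_3d), ncol(counts))
    if (any(!is.finite(sample_area_3d)) || any(sample_area_3d <= 0))
      stop("sample_area_3d must be positive")
  }
  if (!all(is.na(enlargement_factor)) && any(enlargement_factor < 1, na.rm = TRUE))
    stop("enlargement_factor must be >= 1")
  if (!is.na(habitat)) habitat <- match.arg(habitat, INCIDIV_HABITATS)
  if (!is.null(taxon)) {
    taxon <- taxon[rownames(counts)]
    bad <- setdiff(unique(stats::na.omit(taxon)), INCIDIV_TAXA)
    if (length(bad))
      stop("unknown taxon code(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(counts = counts, sample_area_3d = sample_area_3d,
         enlargement_factor = enlargement_factor, frame_area = frame_area,
         habitat = habitat, taxon = taxon),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " phenotypes x ", ncol(x$counts),
      " samples, habitat: ", x$habitat, "\n", sep = "")
  invisible(x)
}

#' Construct a phenotype-by-sampling-unit incidence matrix
#'
#' @param presence binary matrix (phenotype x sampling unit).
#' @param habitat habitat label (see [count_table()]).
#' @return An object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(presence, habitat = NA_character_) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence))) rownames(presence) <- paste0("p", seq_len(nrow(presence)))
  if (is.null(colnames(presence))) colnames(presence) <- paste0("s", seq_len(ncol(presence)))
  if (!all(presence %in% c(0, 1))) stop("presence entries must be 0 or 1")
  if (anyDuplicated(rownames(presence))) stop("phenotype ids must be unique")
  if (!is.na(habitat)) habitat <- match.arg(habitat, INCIDIV_HABITATS)
  structure(list(presence = presence, habitat = habitat), class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("<incidence_matrix> ", nrow(x$presence), " phenotypes x ",
      ncol(x$presence), " sampling units, habitat: ", x$habitat, "\n", sep = "")
  invisible(x)
}

#' Read a phenotype count table from CSV
#'
#' Two dialects are supported. The long dialect has one row per
#' phenotype-sample record with columns `phenotype_id`, `taxon`, `sample_id`,
#' `habitat`, `count`; missing phenotype-sample combinations are zeros. The
#' wide dialect has phenotypes in rows (first column `phenotype_id`, optional
#' second column `taxon`) and samples in the remaining columns.
#'
#' @param path CSV file path (UTF-8, comma separated, with header).
#' @param dialect `"long"` or `"wide"`.
#' @inheritParams count_table
#' @return A [count_table()].
#' @export
read_count_table <- function(path, dialect = c("long", "wide"),
                             sample_area_3d = NULL, enlargement_factor = NA_real_,
                             frame_area = NA_real_) {
  dialect <- match.arg(dialect)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e))
  )
  if (dialect == "long") {
    need <- c("phenotype_id", "taxon", "sample_id", "habitat", "count")
    if (!all(need %in% names(df)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    bad <- which(!df$taxon %in% INCIDIV_TAXA)
    if (length(bad))
      stop("unknown taxon code(s) at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
           ": ", paste(unique(df$taxon[bad]), collapse = ", "))
    if (any(df$count < 0))
      stop("negative count at data line(s) ", paste(which(df$count < 0), collapse = ", "))
    habitat <- unique(df$habitat)
    if (length(habitat) != 1)
      stop("long CSV must contain a single habitat; found: ", paste(habitat, collapse = ", "))
    phen <- unique(df$phenotype_id)
    samp <- unique(df$sample_id)
    m <- matrix(0L, length(phen), length(samp), dimnames = list(phen, samp))
    m[cbind(match(df$phenotype_id, phen), match(df$sample_id, samp))] <- as.integer(df$count)
    taxon <- stats::setNames(df$taxon[!duplicated(df$phenotype_id)], phen)
    count_table(m, sample_area_3d, enlargement_factor, frame_area, habitat, taxon)
  } else {
    if (names(df)[1] != "phenotype_id")
      stop("wide dialect requires first column 'phenotype_id'")
    taxon <- NULL
    first_sample <- 2L
    if (ncol(df) >= 2 && names(df)[2] == "taxon") {
      taxon <- stats::setNames(df$taxon, df$phenotype_id)
      first_sample <- 3L
    }
    m <- as.matrix(df[, first_sample:ncol(df), drop = FALSE])
    storage.mode(m) <- "numeric"
    if (anyNA(m)) stop("malformed CSV '", path, "': non-numeric count cells")
    if (any(m < 0)) stop("negative count in wide table")
    rownames(m) <- df$phenotype_id
    count_table(m, sample_area_3d, enlargement_factor, frame_area, taxon = taxon)
  }
}

#' Write a count table to CSV (wide dialect)
#'
#' @param x a [count_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(phenotype_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Collapse counts to presence/absence incidence
#'
#' Diversity estimation downstream works on phenotype incidence rather than
#' abundance: `presence[i, j] = 1` iff `counts[i, j] > 0`. Phenotypes never
#' observed are retained as all-zero rows (they contribute nothing to any
#' estimator) and reported via `message()`.
#'
#' @param counts a [count_table()].
#' @return An [incidence_matrix()].
#' @export
to_incidence <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  pres <- (counts$counts > 0) * 1L
  zero <- rownames(pres)[rowSums(pres) == 0]
  if (length(zero))
    message("to_incidence: ", length(zero), " all-zero phenotype row(s) retained: ",
            paste(utils::head(zero, 5), collapse = ", "))
  incidence_matrix(pres, counts$habitat)
}

#' Combine seagrass leaf and rhizome samples into the holobiont habitat
#'
#' The seagrass holobiont (leaf canopy plus subsurface rhizome layer) is
#' analysed as the concatenation of the two sets of sampling units: the unit
#' count is additive (T = T_leaves + T_rhizomes) and the phenotype set is the
#' union, with absences filled by zeros.
#'
#' @param leaves [incidence_matrix()] for habitat `PO_leaves`.
#' @param rhizomes [incidence_matrix()] for habitat `PO_rhizomes`.
#' @return An [incidence_matrix()] for habitat `PO_holobiont`.
#' @export
derive_holobiont <- function(leaves, rhizomes) {
  stopifnot(inherits(leaves, "incidence_matrix"), inherits(rhizomes, "incidence_matrix"))
  if (!is.na(leaves$habitat) && leaves$habitat != "PO_leaves")
    stop("'leaves' must have habitat PO_leaves")
  if (!is.na(rhizomes$habitat) && rhizomes$habitat != "PO_rhizomes")
    stop("'rhizomes' must have habitat PO_rhizomes")
  overlap <- intersect(colnames(leaves$presence), colnames(rhizomes$presence))
  if (length(overlap))
    stop("overlapping sample ids: ", paste(overlap, collapse = ", "))
  phen <- union(rownames(leaves$presence), rownames(rhizomes$presence))
  fill <- function(m) {
    out <- matrix(0L, length(phen), ncol(m), dimnames = list(phen, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  incidence_matrix(cbind(fill(leaves$presence), fill(rhizomes$presence)), "PO_holobiont")
}

#' Normalize abundances to habitat and seafloor area
#'
#' Per sample, the habitat-area density is total individuals divided by the
#' sample's 3D substrate surface area; the seafloor density multiplies that by
#' the habitat's enlargement factor. Densities are computed per sample and
#' then averaged (mean and standard error over samples).
#'
#' @param counts a [count_table()] with `sample_area_3d` and
#'   `enlargement_factor` set.
#' @return A list with elements `ind_per_habitat_m2` and `ind_per_seafloor_m2`
#'   (each `c(mean, se)`), `per_sample` (data frame) and `n_samples`.
#' @export
normalize_abundance <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  if (is.null(counts$sample_area_3d)) stop("sample_area_3d not set")
  if (all(is.na(counts$enlargement_factor))) stop("enlargement_factor not set")
  area <- counts$sample_area_3d
  if (any(area <= 0)) stop("zero or negative sample area")
  ef <- rep_len(counts$enlargement_factor, ncol(counts$counts))
  dens <- colSums(counts$counts) / area
  sea <- dens * ef
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(
    ind_per_habitat_m2 = c(mean = mean(dens), se = se(dens)),
    ind_per_seafloor_m2 = c(mean = mean(sea), se = se(sea)),
    per_sample = data.frame(sample_id = colnames(counts$counts),
                            ind_per_habitat_m2 = dens, ind_per_seafloor_m2 = sea,
                            row.names = NULL),
    n_samples = ncol(counts$counts)
  )
}
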