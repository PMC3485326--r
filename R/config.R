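# Run configuration: which barcode belongs to which sample, which locus each
# sample interrogates, the allele references, and the engine thresholds.
#
# The on-disk dialect is YAML:
#
#   params:
#     max_mismatches: 1      # mismatches tolerated in the M13f 17-mer
#     max_edits: ~           # ~ = ceiling(compared_length / 10)
#     min_margin: 1
#   loci:
#     - name: pntAB
#       alleles:
#         - {name: WT,  kind: SNP, anchor: ACGT..., window: ...}
#         - {name: EVO, kind: SNP, anchor: ACGT..., window: ...}
#   samples:
#     - {sample_id: S1, barcode: ACGTAC, locus: pntAB}
#
# An import shim (.xml paths) accepts the equivalent field set in XML
# (<config><params/><loci><locus><allele/>...</locus></loci>
#  <samples><sample/></samples></config>).

#' Assemble a run configuration
#'
#' @param samples Data frame with columns `sample_id`, `barcode`, `locus`.
#' @param loci List of [locus()] objects covering every locus named in
#'   `samples`.
#' @param max_mismatches Mismatches tolerated in the M13f check (default 1).
#' @param max_edits Maximum edit distance for allele assignment; `NULL` uses
#'   `ceiling(compared_length / 10)`.
#' @param min_margin Required distance gap to the runner-up allele.
#' @return An object of class `freq_run_config`.
#' @export
run_config <- function(samples, loci, max_mismatches = 1L, max_edits = NULL,
                       min_margin = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "barcode", "locus") %in% names(samples)))
  if (inherits(loci, "freq_locus")) loci <- list(loci)
  names(loci) <- vapply(loci, `[[`, "", "name")
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        barcode = .check_dna(as.character(samples$barcode),
                                             "barcode", len = .BARCODE_LEN),
                        locus = as.character(samples$locus),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(samples$barcode)) {
    stop("duplicate barcodes across samples", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  missing_loci <- setdiff(samples$locus, names(loci))
  if (length(missing_loci)) {
    stop("samples reference undeclared loci: ",
         paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  stopifnot(max_mismatches >= 0, min_margin >= 0,
            is.null(max_edits) || max_edits >= 0)
  structure(list(
    samples = samples,
    loci = loci,
    params = list(max_mismatches = as.integer(max_mismatches),
                  max_edits = if (is.null(max_edits)) NULL
                              else as.integer(max_edits),
                  min_margin = as.integer(min_margin))
  ), class = "freq_run_config")
}

#' @export
print.freq_run_config <- function(x, ...) {
  cat("Run config:", nrow(x$samples), "samples,", length(x$loci), "loci\n")
  cat("  params: max_mismatches =", x$params$max_mismatches,
      "| max_edits =",
      if (is.null(x$params$max_edits)) "auto" else x$params$max_edits,
      "| min_margin =", x$params$min_margin, "\n")
  invisible(x)
}

#' Read a run configuration from YAML or XML
#'
#' `.yml`/`.yaml` files use the package's native schema (see
#' [write_run_config()]); `.xml` files are accepted through an import shim
#' covering the same field set (alleles, barcodes, parameters).
#'
#' @param path Config file path.
#' @return A `freq_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.xml$", path, ignore.case = TRUE)) {
    .config_from_xml(path)
  } else {
    yaml::read_yaml(path)
  }
  .config_from_list(raw, path)
}

.config_from_list <- function(raw, path = "<config>") {
  for (field in c("loci", "samples")) {
    if (is.null(raw[[field]])) {
      stop(path, ": missing required config section '", field, "'",
           call. = FALSE)
    }
  }
  loci <- lapply(raw$loci, function(l) {
    if (is.null(l$name) || is.null(l$alleles)) {
      stop(path, ": each locus needs 'name' and 'alleles'", call. = FALSE)
    }
    alle <- lapply(l$alleles, function(a) {
      allele(a$name, a$anchor, a$window,
             kind = if (is.null(a$kind)) "SNP" else a$kind)
    })
    locus(l$name, alle)
  })
  samples <- do.call(rbind, lapply(raw$samples, function(s) {
    data.frame(sample_id = s$sample_id, barcode = s$barcode, locus = s$locus,
               stringsAsFactors = FALSE)
  }))
  p <- raw$params
  run_config(samples, loci,
             max_mismatches = if (is.null(p$max_mismatches)) 1L
                              else p$max_mismatches,
             max_edits = p$max_edits,
             min_margin = if (is.null(p$min_margin)) 1L else p$min_margin)
}

.config_from_xml <- function(path) {
  doc <- xml2::read_xml(path)
  num_or_null <- function(x) if (is.na(x) || !nzchar(x)) NULL
                             else as.numeric(x)
  params <- list()
  pnode <- xml2::xml_find_first(doc, ".//params")
  if (!inherits(pnode, "xml_missing")) {
    for (nm in c("max_mismatches", "max_edits", "min_margin")) {
      v <- xml2::xml_text(xml2::xml_find_first(pnode, paste0(".//", nm)))
      params[[nm]] <- num_or_null(v)
    }
  }
  loci <- lapply(xml2::xml_find_all(doc, ".//loci/locus"), function(l) {
    list(name = xml2::xml_attr(l, "name"),
         alleles = lapply(xml2::xml_find_all(l, ".//allele"), function(a) {
           list(name = xml2::xml_attr(a, "name"),
                kind = xml2::xml_attr(a, "kind"),
                anchor = xml2::xml_text(xml2::xml_find_first(a, ".//anchor")),
                window = xml2::xml_text(xml2::xml_find_first(a, ".//window")))
         }))
  })
  samples <- lapply(xml2::xml_find_all(doc, ".//samples/sample"), function(s) {
    list(sample_id = xml2::xml_attr(s, "id"),
         barcode = xml2::xml_attr(s, "barcode"),
         locus = xml2::xml_attr(s, "locus"))
  })
  list(params = params, loci = loci, samples = samples)
}

#' Write a run configuration as YAML
#'
#' @param config A `freq_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "freq_run_config"))
  raw <- list(
    params = config$params[!vapply(config$params, is.null, TRUE)],
    loci = lapply(config$loci, function(l) {
      list(name = l$name,
           alleles = lapply(unname(l$alleles), function(a) {
             list(name = a$name, kind = a$kind, anchor = a$anchor,
                  window = a$window)
           }))
    }),
    samples = lapply(seq_len(nrow(config$samples)), function(i) {
      as.list(config$samples[i, ])
    })
  )
  raw$loci <- unname(raw$loci)
  yaml::write_yaml(raw, path)
  invisible(path)
}
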