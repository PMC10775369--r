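#' Construct a phenotype gating rule
#'
#' A rule names an immune cell type by the markers it must be positive for
#' and the markers it must be negative for.
#'
#' @param name cell-type label.
#' @param positive character vector of markers required positive.
#' @param negative character vector of markers required negative.
#' @return one-row data.frame with list columns \code{positive}, \code{negative}.
#' @export
phenotypeRule <- function(name, positive, negative = character(0)) {
  if (length(intersect(positive, negative)))
    stop("a marker cannot be both positive and negative in rule '", name, "'")
  data.frame(name = name,
             positive = I(list(as.character(positive))),
             negative = I(list(as.character(negative))),
             stringsAsFactors = FALSE)
}

#' Default immune phenotype rule table
#'
#' The canonical marker-combination gates for major immune populations in
#' head-and-neck FNA panels, ordered from most specific to the generic
#' pan-leukocyte fallback. Rules are evaluated in order with first match
#' winning, so e.g. a CD68+ CD66b+ cell is called a neutrophil.
#'
#' @return data.frame of rules (columns name, positive, negative).
#' @export
phenotypeRuleTable <- function() {
  rbind(
    phenotypeRule("CD4+ T cells",         c("CD45", "CD3", "CD4"),    "CD11b"),
    phenotypeRule("CD8+ T cells",         c("CD45", "CD3", "CD8"),    "CD11b"),
    phenotypeRule("Natural killer cells", c("CD45", "CD56"),          c("CD3", "CD11b")),
    phenotypeRule("B cells",              c("CD45", "CD20"),          c("CD3", "CD11b")),
    phenotypeRule("Neutrophils",          c("CD45", "CD11b", "CD66b"), "CD3"),
    phenotypeRule("Macrophages",          c("CD45", "CD11b", "CD68"),  "CD3"),
    phenotypeRule("Dendritic cells",      c("CD45", "CD11b", "CD11c"), "CD3"),
    phenotypeRule("Immune cells",         "CD45",                      "CK56")
  )
}

#' Read a phenotype rule table from CSV or YAML
#'
#' CSV columns: name, positive, negative (markers separated by
#' semicolons or commas within a cell). YAML: a list of
#' \code{\{name:, positive: [..], negative: [..]\}} entries.
#'
#' @param path file path (.csv, .yml or .yaml).
#' @return data.frame of rules as in [phenotypeRuleTable()].
#' @export
readPhenotypeRules <- function(path) {
  ext <- tolower(tools::file_ext(path))
  splitMarkers <- function(s) {
    if (is.null(s) || is.na(s) || !nzchar(s)) return(character(0))
    trimws(strsplit(s, "[;,]")[[1L]])
  }
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    rules <- lapply(seq_len(nrow(df)), function(i)
      phenotypeRule(df$name[i], splitMarkers(df$positive[i]),
                    splitMarkers(df$negative[i])))
  } else if (ext %in% c("yml", "yaml")) {
    lst <- yaml::read_yaml(path)
    rules <- lapply(lst, function(r)
      phenotypeRule(r$name, unlist(r$positive),
                    if (is.null(r$negative)) character(0) else unlist(r$negative)))
  } else stop("unsupported rule file format: ", ext)
  do.call(rbind, rules)
}

# All markers mentioned by a rule table (used for panel validation)
rulesMarkers <- function(rules) {
  unique(c(unlist(rules$positive), unlist(rules$negative)))
}
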