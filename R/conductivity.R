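#' Tissue conductivity table
#'
#' The package ships a low-frequency tissue conductivity table (S/m) in which
#' grouped tissues sharing one literature value are expanded as aliases of a
#' canonical label (e.g. `skull` is an alias of `bone`, `thalamus` of
#' `brain_grey_matter`). The shipped skin value (0.012147 S/m) already
#' embodies a weighted average of skin and subcutaneous adipose tissue, and
#' is used as-is. The electrode model contributes `electrode_pad`
#' (5.9e7 S/m), `sponge` (0.3 S/m) and `air` (0 S/m) entries. Zero
#' conductivity (air, internal air, airway lumina) encodes an insulator:
#' such voxels carry no current in the solver.
#'
#' @return A `conductivity_table`: data frame with columns
#'   `canonical_label`, `aliases` (semicolon-separated), `sigma_S_per_m`,
#'   `source`, carrying a resolved name-to-sigma lookup as an attribute.
#' @examples
#' tab <- default_conductivity_table()
#' sigma_lookup(tab, "brain_grey_matter")  # 0.027512
#' sigma_lookup(tab, "cerebrospinal_fluid")  # 2
#' @export
default_conductivity_table <- function() {
  path <- system.file("extdata", "conductivity_table_v1.csv",
                      package = "tdcsfield", mustWork = TRUE)
  read_conductivity_table(path)
}

#' Read / write a conductivity table (CSV)
#'
#' Sigma values are written with full precision so a round trip is
#' bit-exact.
#'
#' @param path CSV path with columns `canonical_label`, `aliases`,
#'   `sigma_S_per_m`, `source`.
#' @export
read_conductivity_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "character", "character",
                                "character"))
  df$sigma_S_per_m <- as.numeric(df$sigma_S_per_m)
  new_conductivity_table(df)
}

#' @rdname read_conductivity_table
#' @param table a `conductivity_table`.
#' @export
write_conductivity_table <- function(table, path) {
  df <- as.data.frame(table)[, c("canonical_label", "aliases",
                                 "sigma_S_per_m", "source")]
  df$sigma_S_per_m <- vapply(df$sigma_S_per_m,
                             function(x) format(x, digits = 17), "")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_conductivity_table <- function(df) {
  stopifnot(all(c("canonical_label", "aliases", "sigma_S_per_m") %in%
                  names(df)))
  if (anyDuplicated(df$canonical_label))
    stop("duplicate canonical labels in conductivity table")
  if (any(df$sigma_S_per_m < 0)) stop("conductivities must be >= 0")
  lookup <- df$sigma_S_per_m
  names(lookup) <- df$canonical_label
  alias_lists <- strsplit(df$aliases, ";", fixed = TRUE)
  for (i in seq_along(alias_lists)) {
    al <- alias_lists[[i]]
    al <- al[nzchar(al)]
    if (length(al)) {
      extra <- df$sigma_S_per_m[i]
      named <- rep(extra, length(al))
      names(named) <- al
      lookup <- c(lookup, named)
    }
  }
  if (anyDuplicated(names(lookup)))
    stop("a tissue name appears under more than one canonical label")
  structure(df, lookup = lookup, class = c("conductivity_table",
                                           "data.frame"))
}

#' Look up conductivity by tissue name
#'
#' Canonical labels and aliases both resolve.
#' @param table a `conductivity_table`.
#' @param name tissue name (character vector).
#' @return numeric vector of conductivities (S/m).
#' @export
sigma_lookup <- function(table, name) {
  lk <- attr(table, "lookup")
  miss <- setdiff(name, names(lk))
  if (length(miss))
    stop("no conductivity entry for tissue(s): ", paste(miss, collapse = ", "))
  unname(lk[name])
}

#' Map a tissue label volume to a per-voxel conductivity volume
#'
#' Every tissue id present in the volume must resolve to a table entry
#' through the volume's label map (aliases allowed). Air voxels get
#' sigma = 0.
#'
#' @param labels a `label_volume`.
#' @param table a `conductivity_table`.
#' @return A `conductivity_volume`: list with `sigma` (numeric 3-D array,
#'   S/m), `spacing`, `origin`.
#' @export
assign_conductivity <- function(labels, table) {
  stopifnot(inherits(labels, "label_volume"))
  ids_present <- sort(unique(as.integer(labels$labels)))
  counts <- tabulate(match(labels$labels, ids_present),
                     nbins = length(ids_present))
  known <- ids_present %in% labels$label_map
  lk <- attr(table, "lookup")
  nm <- names(labels$label_map)[match(ids_present, labels$label_map)]
  resolvable <- known & nm %in% names(lk)
  if (!all(resolvable)) {
    bad <- which(!resolvable)
    stop("label id(s) without a conductivity entry: ",
         paste(sprintf("id %d (%s, %d voxels)", ids_present[bad],
                       ifelse(is.na(nm[bad]), "unnamed", nm[bad]),
                       counts[bad]), collapse = "; "))
  }
  sig_by_id <- unname(lk[nm])
  sigma <- array(sig_by_id[match(labels$labels, ids_present)],
                 dim = dim(labels$labels))
  structure(list(sigma = sigma, spacing = labels$spacing,
                 origin = labels$origin),
            class = "conductivity_volume")
}
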