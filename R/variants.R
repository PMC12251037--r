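maf_classification_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frame_shift_del",
  Frame_Shift_Ins   = "frame_shift_ins",
  In_Frame_Del      = "in_frame_del",
  In_Frame_Ins      = "in_frame_ins",
  Splice_Site       = "splice_site",
  Silent            = "silent"
)

variant_classifications <- c(unname(maf_classification_map), "other")

# The six standard SNV classes are keyed on the pyrimidine of the mutated
# base pair: purine refs are complemented (A>G is reported as T>C).
snv_class_of <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_snp <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% names(comp) & alt %in% names(comp) & ref != alt
  out <- rep(NA_character_, length(ref))
  flip <- is_snp & ref %in% c("A", "G")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  out[is_snp] <- paste0(r[is_snp], ">", a[is_snp])
  out
}

#' Read a MAF-like variant table
#'
#' Reads tab-separated germline variant calls in Mutation Annotation Format.
#' The tumor-centric column names are accepted but reinterpreted:
#' `Tumor_Sample_Barcode` is the patient id and `Tumor_Seq_Allele2` the
#' alternate allele. Coordinates are MAF convention, 1-based inclusive.
#' Unknown variant classifications are mapped to `"other"` with one warning.
#'
#' @param path Path to the MAF-like TSV. Lines starting with `#` are skipped.
#' @return Data frame of normalized variant records: `patient_id`, `gene`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `variant_key`
#'   (`chrom:pos:ref:alt`), `hgvs_label`, `variant_classification`,
#'   `variant_type` (`SNP`/`DEL`/`INS`), `snv_class` (NA unless SNP),
#'   `zygosity`.
#' @export
read_variants <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  mandatory <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                 "Reference_Allele", "Tumor_Seq_Allele2",
                 "Variant_Classification", "Variant_Type",
                 "Tumor_Sample_Barcode")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) stop("MAF file is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (any(raw$Start_Position <= 0)) stop("MAF positions must be positive (1-based)")

  cls <- maf_classification_map[raw$Variant_Classification]
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) with unrecognized classification mapped to 'other': ",
            paste(unique(raw$Variant_Classification[unknown]), collapse = ", "))
    cls[unknown] <- "other"
  }
  vt <- toupper(raw$Variant_Type)
  if (!all(vt %in% c("SNP", "DEL", "INS"))) {
    stop("unsupported Variant_Type value(s): ",
         paste(setdiff(unique(vt), c("SNP", "DEL", "INS")), collapse = ", "))
  }
  data.frame(
    patient_id = as.character(raw$Tumor_Sample_Barcode),
    gene = raw$Hugo_Symbol,
    chrom = as.character(raw$Chromosome),
    pos = as.integer(raw$Start_Position),
    ref = raw$Reference_Allele,
    alt = raw$Tumor_Seq_Allele2,
    variant_key = paste(raw$Chromosome, raw$Start_Position,
                        raw$Reference_Allele, raw$Tumor_Seq_Allele2, sep = ":"),
    hgvs_label = if ("HGVSc" %in% names(raw)) raw$HGVSc else NA_character_,
    variant_classification = unname(cls),
    variant_type = ifelse(vt == "SNP", "SNP", vt),
    snv_class = ifelse(vt == "SNP",
                       snv_class_of(raw$Reference_Allele, raw$Tumor_Seq_Allele2),
                       NA_character_),
    zygosity = if ("Zygosity" %in% names(raw)) raw$Zygosity else "unknown",
    stringsAsFactors = FALSE
  )
}

#' Read a gene-panel BED file
#'
#' BED convention: 0-based, half-open `[start, end)`. The fourth column is
#' the gene symbol.
#'
#' @param path Path to a headerless 4-column BED file.
#' @return Data frame `chrom`, `start0`, `end0`, `gene`.
#' @export
read_panel_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("panel BED needs 4 columns: chrom, start, end, gene")
  out <- data.frame(chrom = as.character(bed[[1]]), start0 = as.integer(bed[[2]]),
                    end0 = as.integer(bed[[3]]), gene = bed[[4]],
                    stringsAsFactors = FALSE)
  if (any(out$start0 >= out$end0)) stop("BED regions must satisfy start < end")
  out
}

#' Restrict variants to a gene panel
#'
#' Coordinate reconciliation is centralized here: a MAF 1-based position `p`
#' falls in BED half-open region `[start0, end0)` iff `start0 < p <= end0`.
#'
#' @param variants Data frame from [read_variants()].
#' @param regions Data frame from [read_panel_bed()].
#' @return The subset of `variants` overlapping any region.
#' @export
restrict_to_panel <- function(variants, regions) {
  if (nrow(regions) == 0) stop("panel regions must be non-empty")
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    any(regions$chrom == variants$chrom[i] &
          regions$start0 < variants$pos[i] &
          variants$pos[i] <= regions$end0)
  }, logical(1))
  variants[keep, , drop = FALSE]
}

#' Split variants into ClinVar-classified and unclassified sets
#'
#' A variant is "classified" when its normalized key appears in the
#' annotation database with a non-empty clinical-significance string
#' (including "Uncertain significance" — the split is annotated-vs-unknown,
#' not benign-vs-pathogenic). Both sets are returned in full.
#'
#' @param variants Data frame from [read_variants()].
#' @param db Data frame with columns `variant_key` and `clinical_significance`.
#'   Malformed rows (missing/empty key) are skipped with a warning count.
#' @return List with `classified` and `unclassified` data frames (partitioning
#'   the input; `classified` gains a `clinical_significance` column).
#' @export
classify_by_annotation <- function(variants, db) {
  stopifnot(all(c("variant_key", "clinical_significance") %in% names(db)))
  bad <- is.na(db$variant_key) | db$variant_key == "" |
    is.na(db$clinical_significance)
  if (any(bad)) warning(sum(bad), " malformed annotation row(s) skipped")
  db <- db[!bad & db$clinical_significance != "", , drop = FALSE]
  hit <- variants$variant_key %in% db$variant_key
  classified <- variants[hit, , drop = FALSE]
  if (nrow(classified)) {
    classified$clinical_significance <-
      db$clinical_significance[match(classified$variant_key, db$variant_key)]
  }
  list(classified = classified, unclassified = variants[!hit, , drop = FALSE])
}

#' Per-group carrier frequencies of each variant
#'
#' A patient counts once per variant regardless of zygosity or multiplicity.
#' Percentages are `100 * carriers / group size`, rounded to two decimals for
#' display (raw counts are carried alongside).
#'
#' @param variants Data frame from [read_variants()].
#' @param labels Data frame `patient_id`, `label`; defines the group sizes.
#'   Every patient appearing in `variants` must be labeled.
#' @param variant_key Optional single key to restrict the output to.
#' @return Data frame with one row per variant: `variant_key`, `gene`,
#'   `hgvs_label`, `carriers_responder`, `carriers_nonresponder`,
#'   `n_responder`, `n_nonresponder`, `freq_responder`, `freq_nonresponder`.
#' @export
carrier_frequency <- function(variants, labels, variant_key = NULL) {
  unknown <- setdiff(unique(variants$patient_id), labels$patient_id)
  if (length(unknown)) stop("variants reference unlabeled patient(s): ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  lab <- labels[!is.na(labels$label), ]
  n_r <- sum(lab$label == "responder")
  n_n <- sum(lab$label == "non_responder")
  if (n_r == 0 || n_n == 0) stop("both response groups must be non-empty")
  if (!is.null(variant_key)) {
    variants <- variants[variants$variant_key %in% variant_key, , drop = FALSE]
  }
  if (nrow(variants) == 0) {
    return(data.frame(variant_key = character(), gene = character(),
                      hgvs_label = character(), carriers_responder = integer(),
                      carriers_nonresponder = integer(), n_responder = integer(),
                      n_nonresponder = integer(), freq_responder = numeric(),
                      freq_nonresponder = numeric(), stringsAsFactors = FALSE))
  }
  variants$label <- lab$label[match(variants$patient_id, lab$patient_id)]
  keys <- unique(variants$variant_key)
  rows <- lapply(keys, function(k) {
    v <- variants[variants$variant_key == k, ]
    cr <- length(unique(v$patient_id[!is.na(v$label) & v$label == "responder"]))
    cn <- length(unique(v$patient_id[!is.na(v$label) & v$label == "non_responder"]))
    data.frame(variant_key = k, gene = v$gene[1], hgvs_label = v$hgvs_label[1],
               carriers_responder = cr, carriers_nonresponder = cn,
               n_responder = n_r, n_nonresponder = n_n,
               freq_responder = round(100 * cr / n_r, 2),
               freq_nonresponder = round(100 * cn / n_n, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dual-threshold hotspot calls
#'
#' Two nested rules on the per-group carrier frequencies: a variant becomes a
#' node of the pathway graph when it occurs in at least `node_threshold`% of
#' non-responders, and is additionally highlighted when it occurs in at least
#' `highlight_in`% of non-responders AND in strictly less than
#' `highlight_out`% of responders ("at least" inclusive, "less than" strict).
#'
#' @param freqs Data frame from [carrier_frequency()].
#' @param node_threshold,highlight_in,highlight_out Percent thresholds
#'   (defaults 50, 70, 50).
#' @return `freqs` with logical columns `is_graph_node` and `is_highlighted`.
#' @export
call_hotspots <- function(freqs, node_threshold = 50, highlight_in = 70,
                          highlight_out = 50) {
  stopifnot(all(c("freq_responder", "freq_nonresponder") %in% names(freqs)))
  freqs$is_graph_node <- freqs$freq_nonresponder >= node_threshold
  freqs$is_highlighted <- freqs$freq_nonresponder >= highlight_in &
    freqs$freq_responder < highlight_out
  freqs
}

#' Mutation summary of a variant set
#'
#' The count distributions underlying a MAF summary plot plus the
#' gene-by-patient oncomatrix: counts by variant classification, variant type
#' and SNV class; per-gene and per-patient totals; the top-k mutated genes
#' (ties broken by gene symbol); and the oncomatrix whose cell is the
#' variant classification, `"Multi_Hit"` when a gene carries two or more
#' variants in the same patient, or `""`.
#'
#' @param variants Non-empty data frame from [read_variants()].
#' @param top_k Number of genes in the top list (default 10).
#' @return A list with `classification_counts`, `type_counts`,
#'   `snv_class_counts` (named integer vectors), `gene_counts`,
#'   `patient_counts`, `top_genes` (character vector) and `oncomatrix`
#'   (character matrix, genes x patients).
#' @export
summarize_mutations <- function(variants, top_k = 10) {
  if (nrow(variants) == 0) stop("variants must be non-empty")
  cls <- table(factor(variants$variant_classification,
                      levels = variant_classifications))
  typ <- table(factor(variants$variant_type, levels = c("SNP", "DEL", "INS")))
  snv <- table(factor(variants$snv_class,
                      levels = c("C>T", "T>C", "C>G", "C>A", "T>A", "T>G")))
  gene_counts <- sort(table(variants$gene), decreasing = TRUE)
  ord <- order(-as.integer(gene_counts), names(gene_counts))
  gene_counts <- gene_counts[ord]
  patient_counts <- table(variants$patient_id)

  genes <- names(gene_counts)
  patients <- sort(unique(variants$patient_id))
  onc <- matrix("", nrow = length(genes), ncol = length(patients),
                dimnames = list(genes, patients))
  for (i in seq_len(nrow(variants))) {
    g <- variants$gene[i]
    p <- variants$patient_id[i]
    onc[g, p] <- if (onc[g, p] == "") variants$variant_classification[i] else "Multi_Hit"
  }
  list(classification_counts = c(cls),
       type_counts = c(typ),
       snv_class_counts = c(snv),
       gene_counts = c(gene_counts),
       patient_counts = c(patient_counts),
       top_genes = utils::head(genes, top_k),
       oncomatrix = onc)
}

#' Build the pathway-gene-mutation bipartite graph
#'
#' Central nodes are one-carbon-metabolism pathways; peripheral nodes are
#' `(gene, mutation)` pairs for every hotspot passing the graph-node rule.
#' An edge connects a mutation node to each pathway its gene belongs to and is
#' flagged highlighted when the dual-threshold rule fires. Genes missing from
#' the pathway map attach to an `"unassigned"` catch-all node with a warning.
#'
#' @param hotspots Data frame from [call_hotspots()].
#' @param pathway_map Data frame with columns `gene` and `pathway` (one row
#'   per membership; a gene may map to several pathways).
#' @return An [igraph::graph] with vertex attributes `type`
#'   (`"pathway"`/`"mutation"`), `gene`, `label` and edge attribute
#'   `highlighted`.
#' @export
build_pathway_graph <- function(hotspots, pathway_map) {
  stopifnot(all(c("gene", "pathway") %in% names(pathway_map)))
  nodes <- hotspots[hotspots$is_graph_node, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE)
  pathways <- unique(pathway_map$pathway)
  g <- igraph::add_vertices(g, length(pathways), name = pathways,
                            type = "pathway", gene = NA_character_,
                            label = pathways)
  if (nrow(nodes) == 0) {
    warning("no hotspot passes the graph-node threshold; graph has only central nodes")
    return(g)
  }
  unmapped <- setdiff(unique(nodes$gene), pathway_map$gene)
  if (length(unmapped)) {
    warning("gene(s) without a pathway attached to 'unassigned': ",
            paste(unmapped, collapse = ", "))
    g <- igraph::add_vertices(g, 1, name = "unassigned", type = "pathway",
                              gene = NA_character_, label = "unassigned")
    pathway_map <- rbind(pathway_map,
                         data.frame(gene = unmapped, pathway = "unassigned",
                                    stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(nodes))) {
    lab <- if (!is.na(nodes$hgvs_label[i])) nodes$hgvs_label[i] else nodes$variant_key[i]
    vname <- paste(nodes$gene[i], lab)
    g <- igraph::add_vertices(g, 1, name = vname, type = "mutation",
                              gene = nodes$gene[i], label = vname)
    for (pw in pathway_map$pathway[pathway_map$gene == nodes$gene[i]]) {
      g <- igraph::add_edges(g, c(vname, pw), highlighted = nodes$is_highlighted[i])
    }
  }
  g
}

#' Export the pathway graph as GraphML and DOT
#'
#' @param graph Graph from [build_pathway_graph()].
#' @param graphml_path,dot_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_pathway_graph <- function(graph, graphml_path = NULL, dot_path = NULL) {
  if (!is.null(graphml_path)) igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(dot_path)) {
    g <- graph
    if ("highlighted" %in% igraph::edge_attr_names(g)) {
      # DOT has no boolean type; write the flag as 0/1
      igraph::E(g)$highlighted <- as.integer(igraph::E(g)$highlighted)
    }
    igraph::write_graph(g, dot_path, format = "dot")
  }
  invisible(c(graphml_path, dot_path))
}

#' Write variant records as a MAF-like TSV
#'
#' Inverse of [read_variants()] (up to column order); used by the synthetic
#' cohort writer and round-trip tests.
#'
#' @param variants Data frame of variant records.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_variants_maf <- function(variants, path) {
  rev_map <- stats::setNames(names(maf_classification_map), maf_classification_map)
  out <- data.frame(
    Hugo_Symbol = variants$gene,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    End_Position = variants$pos + nchar(variants$ref) - 1L,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Classification = ifelse(variants$variant_classification %in% names(rev_map),
                                    rev_map[variants$variant_classification],
                                    "Unknown"),
    Variant_Type = variants$variant_type,
    Tumor_Sample_Barcode = variants$patient_id,
    HGVSc = variants$hgvs_label,
    Zygosity = variants$zygosity,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
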