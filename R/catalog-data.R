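# Reference tables for the KOG functional classification of human genes and
# the published per-species category summaries. These are frozen upstream
# (the KOG scheme is not recomputed here) and double as parameter sources for
# the synthetic-data generator.

#' The KOG functional class catalog
#'
#' The 25 KOG functional classes, each a single capital letter, grouped into
#' the three broad categories commonly colour-coded Blue (information storage
#' and processing), Black (cellular processes and signaling) and Red
#' (metabolism), plus the poorly characterized classes R and S. Reference
#' per-class human gene counts, mean GC3 and standard deviation are included;
#' they parameterize [table1_spec()] and the worked examples.
#'
#' @return A data.frame with columns `letter`, `name`, `category`
#'   (one of `"BLUE"`, `"BLACK"`, `"RED"`, `"POORLY_CHARACTERIZED"`),
#'   `ref_n`, `ref_mean_gc3`, `ref_sd_gc3`.
#' @examples
#' cat <- kog_classes()
#' subset(cat, category == "RED")$letter
#' @export
kog_classes <- function() {
  df <- rbind(
    data.frame(letter = "A", name = "RNA processing and modification",
               category = "BLUE", ref_n = 600L, ref_mean_gc3 = 0.517, ref_sd_gc3 = 0.151),
    data.frame(letter = "B", name = "Chromatin structure and dynamics",
               category = "BLUE", ref_n = 224L, ref_mean_gc3 = 0.610, ref_sd_gc3 = 0.172),
    data.frame(letter = "J", name = "Translation, ribosomal structure and biogenesis",
               category = "BLUE", ref_n = 1273L, ref_mean_gc3 = 0.545, ref_sd_gc3 = 0.117),
    data.frame(letter = "K", name = "Transcription",
               category = "BLUE", ref_n = 1137L, ref_mean_gc3 = 0.619, ref_sd_gc3 = 0.170),
    data.frame(letter = "L", name = "Replication, recombination and repair",
               category = "BLUE", ref_n = 300L, ref_mean_gc3 = 0.546, ref_sd_gc3 = 0.154),
    data.frame(letter = "D", name = "Cell cycle control, cell division, chromosome partitioning",
               category = "BLACK", ref_n = 267L, ref_mean_gc3 = 0.552, ref_sd_gc3 = 0.160),
    data.frame(letter = "M", name = "Cell wall/membrane/envelope biogenesis",
               category = "BLACK", ref_n = 63L, ref_mean_gc3 = 0.576, ref_sd_gc3 = 0.164),
    data.frame(letter = "N", name = "Cell motility",
               category = "BLACK", ref_n = 26L, ref_mean_gc3 = 0.586, ref_sd_gc3 = 0.163),
    data.frame(letter = "O", name = "Posttranslational modification, protein turnover, chaperones",
               category = "BLACK", ref_n = 1471L, ref_mean_gc3 = 0.557, ref_sd_gc3 = 0.151),
    data.frame(letter = "T", name = "Signal transduction mechanisms",
               category = "BLACK", ref_n = 2214L, ref_mean_gc3 = 0.616, ref_sd_gc3 = 0.158),
    data.frame(letter = "U", name = "Intracellular trafficking, secretion, and vesicular transport",
               category = "BLACK", ref_n = 685L, ref_mean_gc3 = 0.571, ref_sd_gc3 = 0.161),
    data.frame(letter = "V", name = "Defense mechanisms",
               category = "BLACK", ref_n = 1023L, ref_mean_gc3 = 0.527, ref_sd_gc3 = 0.172),
    data.frame(letter = "W", name = "Extracellular structures",
               category = "BLACK", ref_n = 284L, ref_mean_gc3 = 0.588, ref_sd_gc3 = 0.150),
    data.frame(letter = "Y", name = "Nuclear structure",
               category = "BLACK", ref_n = 17L, ref_mean_gc3 = 0.534, ref_sd_gc3 = 0.150),
    data.frame(letter = "Z", name = "Cytoskeleton",
               category = "BLACK", ref_n = 801L, ref_mean_gc3 = 0.638, ref_sd_gc3 = 0.158),
    data.frame(letter = "C", name = "Energy production and conversion",
               category = "RED", ref_n = 403L, ref_mean_gc3 = 0.576, ref_sd_gc3 = 0.153),
    data.frame(letter = "E", name = "Amino acid transport and metabolism",
               category = "RED", ref_n = 499L, ref_mean_gc3 = 0.618, ref_sd_gc3 = 0.154),
    data.frame(letter = "F", name = "Nucleotide transport and metabolism",
               category = "RED", ref_n = 187L, ref_mean_gc3 = 0.588, ref_sd_gc3 = 0.151),
    data.frame(letter = "G", name = "Carbohydrate transport and metabolism",
               category = "RED", ref_n = 469L, ref_mean_gc3 = 0.606, ref_sd_gc3 = 0.150),
    data.frame(letter = "H", name = "Coenzyme transport and metabolism",
               category = "RED", ref_n = 102L, ref_mean_gc3 = 0.563, ref_sd_gc3 = 0.135),
    data.frame(letter = "I", name = "Lipid transport and metabolism",
               category = "RED", ref_n = 410L, ref_mean_gc3 = 0.595, ref_sd_gc3 = 0.154),
    data.frame(letter = "P", name = "Inorganic ion transport and metabolism",
               category = "RED", ref_n = 402L, ref_mean_gc3 = 0.646, ref_sd_gc3 = 0.161),
    data.frame(letter = "Q", name = "Secondary metabolites biosynthesis, transport and catabolism",
               category = "RED", ref_n = 191L, ref_mean_gc3 = 0.591, ref_sd_gc3 = 0.155),
    data.frame(letter = "R", name = "General function prediction only",
               category = "POORLY_CHARACTERIZED", ref_n = 1889L, ref_mean_gc3 = 0.593, ref_sd_gc3 = 0.162),
    data.frame(letter = "S", name = "Function unknown",
               category = "POORLY_CHARACTERIZED", ref_n = 1171L, ref_mean_gc3 = 0.568, ref_sd_gc3 = 0.162)
  )
  rownames(df) <- NULL
  df
}

#' Published per-species KOG category summaries
#'
#' Per-species mean GC3, standard deviation and gene counts of the KOG
#' dataset as a whole and of the Blue, Black and Red categories, for the 14
#' mammalian genomes plus lizard and frog. Used for worked-example
#' arithmetic (category roll-ups) and as a realism reference for the
#' synthetic generator.
#'
#' @return A data.frame with one row per species and columns
#'   `species`, `group`, `kog_gc3`, `kog_sd`, `kog_n`, and for each of
#'   `blue`, `black`, `red`: `_gc3`, `_sd`, `_n`.
#' @export
species_category_reference <- function() {
  cols <- c("species", "group",
            "kog_gc3", "kog_sd", "kog_n",
            "blue_gc3", "blue_sd", "blue_n",
            "black_gc3", "black_sd", "black_n",
            "red_gc3", "red_sd", "red_n")
  m <- list(
    list("H. sapiens", "mammal", 0.584, 0.159, 12942, 0.568, 0.154, 3564, 0.584, 0.163, 6745, 0.604, 0.155, 2663),
    list("G. gorilla", "mammal", 0.609, 0.162, 6268, 0.593, 0.166, 1491, 0.609, 0.166, 3357, 0.626, 0.148, 1420),
    list("P. pygmaeus", "mammal", 0.594, 0.164, 7455, 0.583, 0.167, 1766, 0.593, 0.166, 4012, 0.611, 0.154, 1677),
    list("M. musculus", "mammal", 0.606, 0.114, 7505, 0.596, 0.127, 1780, 0.605, 0.122, 4032, 0.617, 0.101, 1693),
    list("O. cuniculus", "mammal", 0.630, 0.175, 5413, 0.609, 0.179, 1296, 0.629, 0.177, 2867, 0.653, 0.164, 1250),
    list("S. tridecemlineatus", "mammal", 0.565, 0.154, 5455, 0.542, 0.157, 1325, 0.567, 0.155, 2900, 0.584, 0.144, 1230),
    list("B. taurus", "mammal", 0.630, 0.167, 7139, 0.613, 0.171, 1706, 0.632, 0.169, 3794, 0.642, 0.155, 1639),
    list("E. caballus", "mammal", 0.609, 0.164, 7102, 0.594, 0.170, 1646, 0.608, 0.165, 3840, 0.626, 0.153, 1613),
    list("P. vampyrus", "mammal", 0.605, 0.164, 6780, 0.590, 0.170, 1638, 0.607, 0.165, 3607, 0.619, 0.155, 1535),
    list("T. truncatus", "mammal", 0.618, 0.167, 6812, 0.602, 0.172, 1635, 0.617, 0.169, 3634, 0.635, 0.155, 1543),
    list("L. africana", "mammal", 0.583, 0.152, 5704, 0.575, 0.157, 1413, 0.582, 0.153, 3007, 0.595, 0.141, 1284),
    list("D. novemcinctus", "mammal", 0.585, 0.180, 5358, 0.563, 0.181, 1310, 0.585, 0.182, 2832, 0.607, 0.173, 1216),
    list("O. anatinus", "mammal", 0.648, 0.166, 5287, 0.646, 0.169, 1319, 0.646, 0.166, 2734, 0.657, 0.161, 1234),
    list("M. domestica", "mammal", 0.533, 0.145, 3598, 0.529, 0.153, 1641, 0.531, 0.144, 3598, 0.542, 0.137, 1578),
    list("A. carolinensis", "reptile", 0.539, 0.159, 5959, 0.535, 0.158, 3063, 0.546, 0.1655, 1498, 0.539, 0.153, 1398),
    list("X. tropicalis", "amphibian", 0.500, 0.112, 3584, 0.499, 0.112, 1753, 0.499, 0.1174, 961, 0.501, 0.108, 870)
  )
  df <- do.call(rbind, lapply(m, function(r) as.data.frame(setNames(r, cols))))
  rownames(df) <- NULL
  df
}

#' Category roll-up of a published species row
#'
#' Count-weighted mean GC3 of the Blue, Black and Red categories for one
#' species of [species_category_reference()]; reproduces (up to the table's
#' own rounding) the species' overall KOG GC3.
#'
#' @param species Species name as given in `species_category_reference()`.
#' @return A list with `weighted_mean_gc3`, `total_n`, and the published
#'   `kog_gc3` for comparison.
#' @examples
#' category_rollup_reference("G. gorilla")$weighted_mean_gc3  # ~0.609
#' @export
category_rollup_reference <- function(species) {
  ref <- species_category_reference()
  row <- ref[ref$species == species, ]
  if (nrow(row) != 1L)
    stop_kog(sprintf("unknown species '%s'", species), "kogGC3_unknown_species")
  n <- c(row$blue_n, row$black_n, row$red_n)
  g <- c(row$blue_gc3, row$black_gc3, row$red_gc3)
  list(weighted_mean_gc3 = sum(n * g) / sum(n),
       total_n = sum(n),
       kog_gc3 = row$kog_gc3)
}
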