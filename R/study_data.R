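#' Published measurement table of the 16 chondrichthyan specimens
#'
#' The per-specimen anatomical measurements and 2D shape indexes of the 16
#' study specimens (14 species of sharks, rays and a chimaera), as
#' published: body size (total length for sharks and the chimaera, disk
#' width for batoids), olfactory organ dimensions, largest-lamella one-face
#' area, lamellar number, gross and fold-inclusive surface areas with their
#' size-normalized versions, the average and standard deviation of the
#' percentage increase due to secondary folds, the secondary-fold branching
#' index, and the frequency/amplitude/deviation/Brinkhoff silhouette
#' indexes. Published derived columns are carried with the `_pub` suffix so
#' they can serve as regression anchors for the package's own arithmetic.
#'
#' @return data.frame, one row per specimen.
#' @export
study_measurements <- function() {
  d <- utils::read.csv(text = "
id,species,habitat,size_cm,size_kind,raphe_type,organ_width_mm,organ_length_mm,area_largest_mm2,norm_largest_pub,lamellar_number,S_gross_pub,norm_gross_pub,S_folds_pub,norm_folds_pub,pct_mean_pub,pct_sd_pub,branching_index_pub,frequency_pub,amplitude_pub,deviation_pub,brinkhoff_pub
Cm,Chimaera_monstrosa,Bathydemersal,52,TL,round,10,10,12.5,0.46,34,850,31,1819,67,114,8.5,1.96,0.9,0.5,0.53,0.46
Dl,Dalatias_licha,Bathydemersal,35.5,TL,elongated,7,9,7.5,0.60,44,543,43,977,78,80,10.2,1.61,0.61,0.42,0.3,0.27
Es,Etmopterus_spinax,Bathydemersal,37.5,TL,elongated,6,9,8,0.57,52,720,51,2246,160,212,39,2.16,0.98,0.66,0.45,0.61
Gm1,Galeus_melastomus,Bathydemersal,40,TL,elongated,10,14,14,0.88,38,973,61,3240,203,233,57,2.13,1,0.77,0.4,0.69
Gm3,Galeus_melastomus,Bathydemersal,14.5,TL,elongated,5,7,5.5,2.62,40,351,167,1755,835,400,31,2.2,1,0.67,0.34,0.6
Hp,Heptranchias_perlo,Bathydemersal,108,TL,round,13,13,33.5,0.29,34,2278,20,12848,110,464,38,3.29,0.95,0.8,0.52,0.72
Pg,Prionace_glauca,Pelagic-oceanic,43,TL,elongated,8,13,16.5,0.89,95,2825,153,7821,423,177,9,2.04,0.96,0.63,0.42,0.56
Pv,Pteroplatytrygon_violacea,Pelagic-oceanic,107,DW,elongated,13,26,22,0.19,110,4340,38,7378,64,70,12,1.94,0.92,0.39,0.51,0.38
Rb,Raja_brachyura,Demersal,98.5,DW,elongated,14,28,56.2,0.58,61,6300,65,19971,206,217,30,3.67,1,0.67,0.37,0.61
Rm,Raja_miraletus,Demersal,41,DW,elongated,10,22,17,1.01,46,1364,81,5006,298,267,29,3.42,0.89,0.72,0.39,0.59
Rp,Raja_polystigma,Demersal,32,DW,elongated,9,15,15.1,1.47,40,1056,103,4425,432,319,32,3.52,1,0.75,0.31,0.66
Sb,Squalus_blainville,Demersal,53,TL,elongated,7,12,14.1,0.50,47,1177,42,3872,138,229,21,2.03,0.94,0.68,0.49,0.62
Sc7,Scyliorhinus_canicula,Demersal,21,TL,elongated,6,8,7.6,1.72,34,453,103,1586,360,250,37,2.09,0.87,0.69,0.28,0.54
Sc8,Scyliorhinus_canicula,Demersal,35.5,TL,elongated,8,12,13,1.03,34,730,58,3249,258,345,53,1.99,0.98,0.75,0.4,0.67
Sm,Somniosus_microcephalus,Benthopelagic,230,TL,elongated,35,50,220,0.42,44,11700,22,62478,118,434,93,6.92,0.99,0.8,0.36,0.7
Sr,Somniosus_rostratus,Bathydemersal,96,TL,elongated,14,23,44,0.48,36,2200,24,13090,142,495,35,7.9,1,0.82,0.46,0.74
", stringsAsFactors = FALSE, strip.white = TRUE)
  d
}

#' Published Newick tree of the 14 study species
#'
#' The phylogeny of the study species as printed (loose Newick dialect:
#' bracket-wrapped, sibling clades juxtaposed without commas). The three
#' Raja species form a polytomy; the elasmobranch clade is a trichotomy of
#' batoids, squalomorphs and galeomorphs with the chimaera as outgroup.
#'
#' @return the raw Newick string (parse with [parse_newick()], which also
#'   assigns the conventional unit branch lengths).
#' @export
study_tree_newick <- function() {
  paste0("[Chimaera_monstrosa (((Raja_brachyura, Raja_polystigma, ",
         "Raja_miraletus), Pteroplatytrygon_violacea) ((Heptranchias_perlo, ",
         "(Squalus_blainville, (Dalatias_licha, (Etmopterus_spinax, ",
         "(Somniosus_rostratus, Somniosus_microcephalus)))))) ",
         "((Scyliorhinus_canicula, (Galeus_melastomus, Prionace_glauca))))]")
}

#' Published tree as a phylo object with unit branch lengths
#'
#' @return an `ape` phylo object, 14 tips, every branch length 1.
#' @export
study_tree <- function() {
  parse_newick(study_tree_newick(), default_brlen = 1)
}

#' Morphometric trait matrix for the phylogenetic PCA
#'
#' The five shape-descriptive traits per specimen: size-normalized
#' largest-lamella area (100 a_L / size^2), lamellar number, average
#' percentage increase due to secondary folds, secondary-fold branching
#' index, and Brinkhoff index. Gross and fold-inclusive organ areas are
#' deliberately excluded (their estimation algorithm is biased across
#' raphe shapes). For the two species sampled twice only the larger
#' specimen is kept (Sc8, Gm1), and rows are labelled by species to match
#' the tree tips, leaving 14 specimens.
#'
#' @param measurements a measurement table shaped like
#'   [study_measurements()] (the default).
#' @param drop_smaller_duplicates keep only the largest specimen per
#'   species (default TRUE).
#' @return numeric matrix, specimens x 5 traits, rownames = species.
#' @export
study_traits <- function(measurements = study_measurements(),
                         drop_smaller_duplicates = TRUE) {
  m <- measurements
  if (drop_smaller_duplicates) {
    keep <- unlist(lapply(split(seq_len(nrow(m)), m$species), function(i)
      i[which.max(m$size_cm[i])]))
    m <- m[sort(keep), , drop = FALSE]
  }
  X <- cbind(norm_largest = m$norm_largest_pub,
             lamellar_number = m$lamellar_number,
             pct_increase = m$pct_mean_pub,
             branching_index = m$branching_index_pub,
             brinkhoff = m$brinkhoff_pub)
  rownames(X) <- m$species
  X
}
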