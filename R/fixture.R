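# 25-tip apid-like chronogram. Exemplar terminals stand for the clades whose
# social behavior they represent; ages (My) at key nodes: corbiculate crown
# 87, Bombini+Meliponini 80, Apini+Euglossini 84, Meliponini crown 58,
# Apini crown 22, Bombini crown 21, orchid-bee crown 28, allodapine crown 53.
apid_newick <- paste0(
  "(((Centris_sp:80,Epicharis_sp:80):20,(Anthophora_sp:70,Amegilla_sp:70):30):20,",
  "((Nomada_sp:40,Epeolus_sp:40):70,(((Xylocopa_virginica:30,Xylocopa_sonorina:30):60,",
  "((Ceratina_calcarata:35,Ceratina_japonica:35):40,(Exoneura_sp:53,",
  "(Allodape_sp:40,Braunsapis_sp:40):13):22):15):15,(((Psithyrus_sp:45,",
  "(Bombus_terrestris:21,Bombus_impatiens:21):24):35,(Melipona_sp:58,",
  "(Trigona_sp:30,Tetragonula_sp:30):28):22):7,((Apis_mellifera:22,Apis_dorsata:22):62,",
  "(Exaerete_sp:35,(Euglossa_imperialis:28,(Eulaema_nigrita:15,Eufriesea_sp:15):13):7):49):3):18):5):10);")

apid_codings_complex <- c(
  Centris_sp = "0", Epicharis_sp = "0", Anthophora_sp = "0", Amegilla_sp = "0",
  Nomada_sp = "4", Epeolus_sp = "4",
  Xylocopa_virginica = "01", Xylocopa_sonorina = "01",
  Ceratina_calcarata = "012", Ceratina_japonica = "012",
  Exoneura_sp = "12", Allodape_sp = "12", Braunsapis_sp = "12",
  Psithyrus_sp = "4",
  Bombus_terrestris = "2", Bombus_impatiens = "2",
  Melipona_sp = "3", Trigona_sp = "3", Tetragonula_sp = "3",
  Apis_mellifera = "3", Apis_dorsata = "3",
  Exaerete_sp = "4",
  Euglossa_imperialis = "0", Eulaema_nigrita = "01", Eufriesea_sp = "0")

# traditional scheme has no "social" state: social codings collapse onto the
# neighboring levels (solitary for the carpenter and orchid bees,
# primitively eusocial for the allodapines)
apid_codings_traditional <- c(
  Centris_sp = "0", Epicharis_sp = "0", Anthophora_sp = "0", Amegilla_sp = "0",
  Nomada_sp = "4", Epeolus_sp = "4",
  Xylocopa_virginica = "0", Xylocopa_sonorina = "0",
  Ceratina_calcarata = "02", Ceratina_japonica = "02",
  Exoneura_sp = "2", Allodape_sp = "2", Braunsapis_sp = "2",
  Psithyrus_sp = "4",
  Bombus_terrestris = "2", Bombus_impatiens = "2",
  Melipona_sp = "3", Trigona_sp = "3", Tetragonula_sp = "3",
  Apis_mellifera = "3", Apis_dorsata = "3",
  Exaerete_sp = "4",
  Euglossa_imperialis = "0", Eulaema_nigrita = "0", Eufriesea_sp = "0")

#' Apid-like synthetic fixture
#'
#' A deterministic 25-tip ultrametric tree (depth 120 My) whose terminals
#' stand for the corbiculate tribes (orchid bees solitary/communal, bumble
#' bees primitively eusocial, honey bees and stingless bees advanced
#' eusocial), the carpenter bees *Xylocopa* (solitary or social) and
#' *Ceratina* (solitary, social or primitively eusocial), the allodapines
#' (social or primitively eusocial), cleptoparasitic clades, and solitary
#' outgroups — exercising every coding feature (polymorphic tips, parasitic
#' state, both built-in schemes). Key clade ages follow the published apid
#' chronology (corbiculate crown 87 My).
#'
#' @param sample_size trees in the jittered pseudo-posterior sample.
#' @param jitter branch-length jitter of the sample (0 = identical copies).
#' @param seed seed for the jitter.
#' @return list with `tree` (`phylo`), `trees` ([tree_sample]),
#'   `traditional` and `complex` (`coding_scheme`s with tips attached),
#'   `queries` (clade-query tibble: seven key nodes), `true_ages` (tibble of
#'   the fixture's clade ages).
#' @export
make_apid_fixture <- function(sample_size = 100, jitter = 0.05, seed = 2026) {
  tree <- ape::read.tree(text = apid_newick)
  set.seed(seed)
  trees <- make_chronogram_sample(tree, sample_size, jitter)
  traditional <- set_tips(builtin_scheme("traditional"),
                          tibble(taxon = names(apid_codings_traditional),
                                 symbols = unname(apid_codings_traditional)))
  complex <- set_tips(builtin_scheme("complex"),
                      tibble(taxon = names(apid_codings_complex),
                             symbols = unname(apid_codings_complex)))
  corb <- c("Apis_mellifera", "Melipona_sp", "Bombus_terrestris",
            "Euglossa_imperialis")
  queries <- dplyr::bind_rows(
    clade_query(corb, "corbiculates"),
    clade_query(c("Bombus_terrestris", "Melipona_sp"), "Bombini+Meliponini"),
    clade_query(c("Apis_mellifera", "Euglossa_imperialis"), "Apini+Euglossini"),
    clade_query(c("Bombus_terrestris", "Bombus_impatiens"), "Bombini"),
    clade_query(c("Melipona_sp", "Trigona_sp", "Tetragonula_sp"), "Meliponini"),
    clade_query(c("Apis_mellifera", "Apis_dorsata"), "Apini"),
    clade_query(c("Euglossa_imperialis", "Eulaema_nigrita", "Eufriesea_sp"),
                "Euglossini"))
  true_ages <- tibble(
    clade = c("corbiculates", "Bombini+Meliponini", "Apini+Euglossini",
              "Bombini", "Meliponini", "Apini", "Euglossini", "allodapines"),
    age = c(87, 80, 84, 21, 58, 22, 28, 53))
  list(tree = tree, trees = trees, traditional = traditional,
       complex = complex, queries = queries, true_ages = true_ages)
}
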