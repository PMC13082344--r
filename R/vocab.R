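# Closed vocabularies of the staging system and the anatomical gazetteers the
# extractor and report renderer share.  Everything here is a constant; the
# staging rules live in staging.R.

#' Label vocabularies
#'
#' Closed label sets for the three TNM components and the clinical stage
#' groups, in their canonical display order.
#'
#' @return Character vector of labels.
#' @export
#' @examples
#' t_levels()
t_levels <- function() {
  c("T0", "Tis", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T3", "T4", "Tx")
}

#' @rdname t_levels
#' @export
n_levels <- function() c("N0", "N1", "N2", "N3", "Nx")

#' @rdname t_levels
#' @export
m_levels <- function() c("M0", "M1a", "M1b", "M1c", "Mx")

#' @rdname t_levels
#' @export
stage_levels <- function() {
  c("0", "IA1", "IA2", "IA3", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC",
    "IVA", "IVB", "occult", "indeterminate")
}

lobe_levels <- function() c("RUL", "RML", "RLL", "LUL", "LLL", "unknown")

modality_levels <- function() c("pet_ct", "contrast_ct", "neither")

evidence_levels <- function() c("confirmatory", "nonspecific")

# Invasion-site tiers.  major_vessel covers aorta, SVC, IVC, the main
# pulmonary arteries and the intrapericardial pulmonary veins; chest_wall
# includes Pancoast tumors.
.t4_sites <- c("diaphragm", "mediastinum", "heart", "major_vessel", "trachea",
               "recurrent_laryngeal_nerve", "esophagus", "vertebral_body",
               "carina")
.t3_sites <- c("parietal_pleura", "chest_wall", "phrenic_nerve", "pericardium",
               "distal_vessel_main_stem")
.t2_sites <- c("main_bronchus", "visceral_pleura")

#' Invasion sites and their T tier
#'
#' @return Data frame with columns `code` and `tier` (one of `T4_SITE`,
#'   `T3_SITE`, `T2_SITE`); each site belongs to exactly one tier.
#' @export
invasion_sites <- function() {
  data.frame(
    code = c(.t4_sites, .t3_sites, .t2_sites),
    tier = rep(c("T4_SITE", "T3_SITE", "T2_SITE"),
               c(length(.t4_sites), length(.t3_sites), length(.t2_sites))),
    stringsAsFactors = FALSE
  )
}

invasion_tier <- function(code) {
  tab <- invasion_sites()
  tab$tier[match(code, tab$code)]
}

# Nodal-station tiers
.n1_stations <- c("ipsilateral_peribronchial", "ipsilateral_hilar",
                  "ipsilateral_intrapulmonary")
.n2_stations <- c("ipsilateral_mediastinal", "subcarinal")
.n3_stations <- c("contralateral_mediastinal", "contralateral_hilar",
                  "scalene_either_side", "supraclavicular_either_side")

#' Nodal stations and their N tier
#'
#' @return Data frame with columns `code` and `n_tier` (`N1_STATION`,
#'   `N2_STATION` or `N3_STATION`).
#' @export
nodal_stations <- function() {
  data.frame(
    code = c(.n1_stations, .n2_stations, .n3_stations),
    n_tier = rep(c("N1_STATION", "N2_STATION", "N3_STATION"),
                 c(length(.n1_stations), length(.n2_stations),
                   length(.n3_stations))),
    stringsAsFactors = FALSE
  )
}

station_tier <- function(code) {
  tab <- nodal_stations()
  tab$n_tier[match(code, tab$code)]
}

# ---------------------------------------------------------------------------
# Gazetteers: surface form -> code tables per language.  Ordered so that a
# longest-match scan resolves nested surfaces (zh: "主支气管" before "气管",
# "对侧纵隔" before "纵隔", "肾上腺" before "肾").

.gaz <- function(surface, code) {
  data.frame(surface = surface, code = code, stringsAsFactors = FALSE)
}

site_gazetteer <- function(language = c("zh", "en")) {
  language <- match.arg(language)
  if (language == "zh") {
    .gaz(
      c("左主支气管", "右主支气管", "主支气管",
        "脏层胸膜", "壁层胸膜",
        "远端血管主干",
        "喉返神经", "膈神经",
        "上腔静脉", "下腔静脉", "主动脉", "肺动脉干", "大血管",
        "纵隔", "膈肌", "心脏", "气管", "食管", "椎体", "隆突",
        "心包", "胸壁"),
      c("main_bronchus", "main_bronchus", "main_bronchus",
        "visceral_pleura", "parietal_pleura",
        "distal_vessel_main_stem",
        "recurrent_laryngeal_nerve", "phrenic_nerve",
        "major_vessel", "major_vessel", "major_vessel", "major_vessel",
        "major_vessel",
        "mediastinum", "diaphragm", "heart", "trachea", "esophagus",
        "vertebral_body", "carina",
        "pericardium", "chest_wall")
    )
  } else {
    .gaz(
      c("main bronchus", "visceral pleura", "parietal pleura",
        "distal vessel main stem", "recurrent laryngeal nerve",
        "phrenic nerve", "superior vena cava", "inferior vena cava",
        "aorta", "main pulmonary artery", "major vessel",
        "mediastinum", "diaphragm", "heart", "trachea", "esophagus",
        "vertebral body", "vertebra", "carina", "pericardium",
        "chest wall"),
      c("main_bronchus", "visceral_pleura", "parietal_pleura",
        "distal_vessel_main_stem", "recurrent_laryngeal_nerve",
        "phrenic_nerve", "major_vessel", "major_vessel",
        "major_vessel", "major_vessel", "major_vessel",
        "mediastinum", "diaphragm", "heart", "trachea", "esophagus",
        "vertebral_body", "vertebral_body", "carina", "pericardium",
        "chest_wall")
    )
  }
}

station_gazetteer <- function(language = c("zh", "en")) {
  language <- match.arg(language)
  if (language == "zh") {
    .gaz(
      c("对侧纵隔", "对侧肺门", "锁骨上", "斜角肌",
        "隆突下", "同侧纵隔", "纵隔",
        "同侧肺门", "肺门", "支气管旁", "肺内"),
      c("contralateral_mediastinal", "contralateral_hilar",
        "supraclavicular_either_side", "scalene_either_side",
        "subcarinal", "ipsilateral_mediastinal", "ipsilateral_mediastinal",
        "ipsilateral_hilar", "ipsilateral_hilar",
        "ipsilateral_peribronchial", "ipsilateral_intrapulmonary")
    )
  } else {
    .gaz(
      c("contralateral mediastinal", "contralateral hilar",
        "supraclavicular", "scalene",
        "subcarinal", "ipsilateral mediastinal", "mediastinal",
        "ipsilateral hilar", "hilar", "peribronchial", "intrapulmonary"),
      c("contralateral_mediastinal", "contralateral_hilar",
        "supraclavicular_either_side", "scalene_either_side",
        "subcarinal", "ipsilateral_mediastinal", "ipsilateral_mediastinal",
        "ipsilateral_hilar", "ipsilateral_hilar",
        "ipsilateral_peribronchial", "ipsilateral_intrapulmonary")
    )
  }
}

organ_gazetteer <- function(language = c("zh", "en")) {
  language <- match.arg(language)
  if (language == "zh") {
    .gaz(
      c("肾上腺", "肝脏", "肝", "脑", "颅内", "骨", "肾", "脾", "胰腺"),
      c("adrenal", "liver", "liver", "brain", "brain", "bone", "kidney",
        "spleen", "pancreas")
    )
  } else {
    .gaz(
      c("adrenal", "liver", "hepatic", "brain", "intracranial", "bone",
        "kidney", "renal", "spleen", "pancreas"),
      c("adrenal", "liver", "liver", "brain", "brain", "bone", "kidney",
        "kidney", "spleen", "pancreas")
    )
  }
}

lobe_gazetteer <- function(language = c("zh", "en")) {
  language <- match.arg(language)
  if (language == "zh") {
    .gaz(
      c("右肺上叶", "右肺中叶", "右肺下叶", "左肺上叶", "左肺下叶"),
      c("RUL", "RML", "RLL", "LUL", "LLL")
    )
  } else {
    .gaz(
      c("right upper lobe", "right middle lobe", "right lower lobe",
        "left upper lobe", "left lower lobe"),
      c("RUL", "RML", "RLL", "LUL", "LLL")
    )
  }
}

# Tumor-denoting words: a size is only taken as the primary tumor diameter
# when one of these co-occurs in the sentence (Table-1-style guard against
# sizes of nonneoplastic nodules).
tumor_words <- function(language = c("zh", "en")) {
  language <- match.arg(language)
  if (language == "zh") c("肿块", "肿瘤", "占位", "病灶", "原发肿瘤", "原发灶")
  else c("mass", "tumor", "tumour", "lesion", "primary")
}
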