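# Default rule configuration for certificate auditing.
#
# All terms are stored normalized: lowercase, no diacritics, single spaces.
# Spanish clinical vocabulary with a few English aliases. The lexicons are an
# explicit, overridable stand-in for the clinical judgment a human reviewer
# applies; they are deliberately small and exact-match so that every flag a
# detector raises can be traced to a configured term.
version: 1

# Separators that indicate more than one condition written on a single line.
conjunction_tokens: [";", ",", " y ", " con ", " and "]

# Conditions of no public-health value when entered as the underlying cause:
# modes of dying, organ failures, symptoms/signs, pathophysiological findings.
ill_defined_lexicon:
  - paro cardiaco
  - paro respiratorio
  - paro cardiorrespiratorio
  - insuficiencia cardiaca
  - insuficiencia hepatica
  - insuficiencia respiratoria
  - falla organica multiple
  - shock
  - choque
  - hematemesis
  - disnea
  - fiebre
  - senilidad
  - cardiac arrest
  - respiratory arrest
  - heart failure
  - hepatic failure

# Tokens treated as abbreviations wherever they appear (case-insensitive).
abbreviation_lexicon:
  [iam, vih, epoc, acv, tbc, hta, dm2, erc, tec, fmo, icc, hda, evc]

# All-capitals tokens of length 2-6 are flagged as abbreviations unless
# whitelisted here (stored lowercase, compared case-insensitively).
abbreviation_whitelist: [ii, iii]

# Exact normalized condition text -> condition category, used by the
# causal-sequence rule. Conditions absent from this map are treated as
# compatible with anything.
categories:
  sepsis: systemic_infection
  septicemia: systemic_infection
  neumonia bacteriana: respiratory_infection
  bronconeumonia: respiratory_infection
  tuberculosis pulmonar: tuberculosis
  enfermedad pulmonar obstructiva cronica: chronic_respiratory
  diabetes mellitus tipo 1: diabetes
  diabetes mellitus tipo 2: diabetes
  diabetes mellitus: diabetes
  insuficiencia renal cronica: renal
  enfermedad renal cronica: renal
  infarto agudo de miocardio: ischemic_heart
  cardiopatia isquemica: ischemic_heart
  hemorragia intracerebral: cerebrovascular
  accidente cerebrovascular isquemico: cerebrovascular
  hipertension arterial esencial: hypertension
  hipertension arterial: hypertension
  hipertension secundaria: hypertension
  neoplasia maligna de estomago: neoplasm
  neoplasia maligna de pulmon: neoplasm
  neoplasia maligna de colon: neoplasm
  neoplasia maligna: neoplasm
  cirrosis hepatica: liver
  traumatismo: external_injury
  politraumatismo: external_injury
  fractura de femur: external_injury
  traumatismo encefalocraneano por accidente de transito: external_injury
  paro cardiaco: ill_defined
  paro respiratorio: ill_defined
  paro cardiorrespiratorio: ill_defined
  insuficiencia cardiaca: ill_defined
  insuficiencia hepatica: ill_defined
  insuficiencia respiratoria: ill_defined
  falla organica multiple: ill_defined
  shock: ill_defined
  choque: ill_defined
  hematemesis: ill_defined
  disnea: ill_defined
  fiebre: ill_defined
  senilidad: ill_defined

# Clinically accepted cause -> consequence pairs over the categories above.
# The sequence rule accepts any adjacent pair in the reflexive transitive
# closure of this relation; the relation itself must be acyclic.
causal_relation:
  - [diabetes, renal]
  - [diabetes, ischemic_heart]
  - [diabetes, cerebrovascular]
  - [diabetes, systemic_infection]
  - [hypertension, ischemic_heart]
  - [hypertension, cerebrovascular]
  - [hypertension, renal]
  - [chronic_respiratory, respiratory_infection]
  - [tuberculosis, respiratory_infection]
  - [tuberculosis, systemic_infection]
  - [respiratory_infection, systemic_infection]
  - [neoplasm, systemic_infection]
  - [liver, systemic_infection]
  - [external_injury, systemic_infection]
  - [renal, ischemic_heart]

# Categories that cannot plausibly initiate the chain of events; a UCOD in
# one of these categories is flagged as an incorrect sequence.
non_initiating_categories: [systemic_infection]

# Under-specified diagnosis rules (additional-error subtypes) ----------------

# Indicators that the underlying cause is an external cause / injury.
external_cause_terms: [traumatismo, politraumatismo, fractura, quemadura, intoxicacion, ahogamiento, herida]
# An external-cause UCOD must carry at least one intent or mechanism term.
intent_terms: [accidental, accidente, suicidio, homicidio, agresion, intencional, autoinfligida]
mechanism_terms: [transito, caida, arma de fuego, arma blanca, sumersion, precipitacion]

# Neoplasm statements must carry both a behaviour and a site qualifier.
neoplasm_terms: [neoplasia, tumor, cancer]
neoplasm_behaviour_terms: [maligna, maligno, benigna, benigno, in situ, metastasico, metastasica]
neoplasm_site_terms: [estomago, pulmon, colon, mama, prostata, higado, piel, rinon, hueso, cerebro, cuello uterino]

# Hypertension / diabetes must be specified by type.
hypertension_terms: [hipertension]
hypertension_qualifiers: [esencial, primaria, secundaria]
diabetes_terms: [diabetes]
diabetes_qualifiers: [tipo 1, tipo 2, insulinodependiente, no insulinodependiente]

# Fully specified conditions that could serve as underlying cause; when one
# appears in Part 2 while Part 1's UCOD is ill-defined, the certificate is
# flagged (underlying cause recorded in the wrong part).
ucod_capable_terms:
  - tuberculosis pulmonar
  - neoplasia maligna de estomago
  - neoplasia maligna de pulmon
  - neoplasia maligna de colon
  - diabetes mellitus tipo 1
  - diabetes mellitus tipo 2
  - hipertension arterial esencial
  - enfermedad pulmonar obstructiva cronica
  - cirrosis hepatica
  - infarto agudo de miocardio
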