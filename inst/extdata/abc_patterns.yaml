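# Default pattern configuration for the automated Addiction Behaviors
# Checklist (ABC). The full published lexicons and expression set are not
# public; this default is a RECONSTRUCTION built from the 20 ABC item
# concepts, the documented item-2 stems and opioid-term fragments (including
# their intentional misspellings "opiod", "stockpil", "analges"), and a
# 7-term negation lexicon. Sites should review and extend it for their own
# documentation styles. All expressions are case-insensitive. Lexicon
# entries are matched as left-anchored word stems ("narc" matches
# "narcotics"); negation entries as whole words/phrases.
lexicons:
  opioid_terms:
    - pain med
    - pain pill
    - opioid
    - opiod
    - narc
    - analges
  drug_names:
    - oxycodone
    - oxycontin
    - hydrocodone
    - vicodin
    - norco
    - lortab
    - percocet
    - morphine
    - fentanyl
    - codeine
    - tramadol
    - methadone
    - hydromorphone
    - dilaudid
    - oxymorphone
    - opana
    - buprenorphine
    - suboxone
    - meperidine
    - demerol
    - heroin
  negation_terms:
    - denies
    - denied
    - 'no'
    - 'not'
    - without
    - never
    - negative for
items:
  - item_id: 1
    label: Used illicit drugs or evidences problem drinking
    core_expressions:
      - 'illicit (drug|substance)s?'
      - 'problem drinking'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 2
    label: Has hoarded medications
    core_expressions:
      - '\b(hoard\w*|stash\w*|stockpil\w*)'
      - '\b(left over|leftover|storing)\b'
    require_opioid_context: true
    opioid_order_constraint: trigger_before_term
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 3
    label: Used more medication than prescribed
    core_expressions:
      - '\b(more|exceed\w*)\b.{0,40}\bthan (prescribed|directed)\b'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 4
    label: Ran out of medications early
    core_expressions:
      - '\b(ran|run|running) out\b.{0,40}\bearl(y|ier)\b'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 5
    label: Increased use of narcotics
    core_expressions:
      - '\b(increas\w+|escalat\w+)\b.{0,20}\b(use|usage|dose|dosing|intake)\b'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 6
    label: Used analgesics PRN against time-contingent prescription
    core_expressions:
      - '\bprn\b.{0,40}\b(instead of|rather than)\b'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 7
    label: Received narcotics from more than one provider
    core_expressions:
      - '\b(multiple|several)\b.{0,20}\b(provider|prescriber|doctor|physician)'
      - 'doctor.?shopping'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 8
    label: Bought medications on the street
    core_expressions:
      - '\b(bought|buy\w*|purchas\w+|obtain\w+)\b.{0,40}\b(on|off) the street'
      - '\bfrom a (dealer|street)'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 9
    label: Appears sedated or confused
    core_expressions:
      - '\b(sedated|slurred speech|somnolent|nodding off)'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 10
    label: Expresses worry about addiction
    core_expressions:
      - '\b(worr\w+|concern\w+|afraid|fear\w*)\b.{0,30}\b(addict\w+|dependen\w+)'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 11
    label: Expresses concern about future availability of medication
    core_expressions:
      - '\b(concern\w+|worr\w+|anxious)\b.{0,15}\babout\b.{0,40}\b(refill|supply|running out|availability)'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 12
    label: Reports lost or stolen medications
    core_expressions:
      - '\b(lost|stolen|misplaced)\b.{0,30}\b(med\w+|pill\w+|prescription\w*|script\w*)'
      - '\b(med\w+|pill\w+|prescription\w*|script\w*)\b.{0,30}\b(was|were) (lost|stolen|misplaced)'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 13
    label: Indicates needing or having to have analgesic medications
    core_expressions:
      - '\b(needs|must have)\b.{0,25}\b(analgesic\w*|pain med\w*|opioid\w*|narcotic\w*)'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 14
    label: Analgesic medications the predominant issue of visit
    core_expressions:
      - '\b(predominant\w*|dominat\w+)\b.{0,40}\b(visit|discussion|appointment)'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 15
    label: Noncompliant with other recommended therapies
    core_expressions:
      - '\bnon.?complian\w+'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 16
    label: Requests early refills
    core_expressions:
      - '\bearl\w* refill\w*'
      - '\brefill\w*\b.{0,30}\bearl(y|ier)\b'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 17
    label: Manifests opioid withdrawal symptoms
    core_expressions:
      - '\b(withdrawal (symptom|sign)\w*|opioid withdrawal|narcotic withdrawal)'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
  - item_id: 18
    label: Indicates inability to function without medications
    core_expressions:
      - '\b(cannot|can.?t|unable to) (function|cope|manage) without'
    require_opioid_context: true
    opioid_order_constraint: trigger_before_term
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 19
    label: Significant other expresses concern about medication use
    core_expressions:
      - '\b(wife|husband|spouse|partner|family|significant other|daughter|son)\b.{0,50}\b(concern\w+|worr\w+)'
    require_opioid_context: true
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes:
      - discharge instructions
  - item_id: 20
    label: Difficulty with medication agreement
    core_expressions:
      - '\b(violat\w+|breach\w*|broke|difficult\w+)\b.{0,40}\b(agreement|contract)'
      - '\b(agreement|contract) violation'
    require_opioid_context: false
    opioid_order_constraint: none
    negation_enabled: true
    exclusion_prefixes: []
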