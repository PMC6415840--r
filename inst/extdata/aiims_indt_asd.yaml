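# Default structural definition of the AIIMS-Modified INDT-ASD instrument.
#
# Section A: 28 questions across 7 subdomains (criterion clusters).
# Section B: the two mandatory items (onset in the early developmental
# period; impairment of daily functioning).
#
# Prompts are structural placeholders: scoring depends only on the
# question/subdomain structure, the abnormal-response polarity and the
# rater precedence.  Sites holding the published instrument booklet should
# replace prompts, per-question polarity/precedence and per-subdomain
# abnormality thresholds with the booklet's actual rules; the defaults
# below (abnormal_response "no", precedence "investigator",
# abnormal_min_count 1) are explicit, editable placeholders.
#
# Polarity values are quoted ("yes"/"no") because bare yes/no are YAML
# booleans.
name: AIIMS-Modified INDT-ASD
version: "1.0"
mandatory_b_items:
  - onset_early_development
  - functional_impairment
subdomains:
  - id: A1a
    label: Deficits in social-emotional reciprocity
    abnormal_min_count: 1
    questions:
      - {id: A1a.1, prompt: "Social-emotional reciprocity item 1", abnormal_response: "no", precedence: investigator}
      - {id: A1a.2, prompt: "Social-emotional reciprocity item 2", abnormal_response: "no", precedence: investigator}
      - {id: A1a.3, prompt: "Social-emotional reciprocity item 3", abnormal_response: "no", precedence: investigator}
      - {id: A1a.4, prompt: "Social-emotional reciprocity item 4", abnormal_response: "no", precedence: investigator}
      - {id: A1a.5, prompt: "Social-emotional reciprocity item 5", abnormal_response: "no", precedence: investigator}
      - {id: A1a.6, prompt: "Social-emotional reciprocity item 6", abnormal_response: "no", precedence: investigator}
      - {id: A1a.7, prompt: "Social-emotional reciprocity item 7", abnormal_response: "no", precedence: investigator}
      - {id: A1a.8, prompt: "Social-emotional reciprocity item 8", abnormal_response: "no", precedence: investigator}
  - id: A1b
    label: Deficits in non-verbal communication
    abnormal_min_count: 1
    questions:
      - {id: A1b.1, prompt: "Non-verbal communication item 1", abnormal_response: "no", precedence: investigator}
      - {id: A1b.2, prompt: "Non-verbal communication item 2", abnormal_response: "no", precedence: investigator}
      - {id: A1b.3, prompt: "Non-verbal communication item 3", abnormal_response: "no", precedence: investigator}
      - {id: A1b.4, prompt: "Non-verbal communication item 4", abnormal_response: "no", precedence: investigator}
  - id: A1c
    label: Deficits in developing and maintaining relationships
    abnormal_min_count: 1
    questions:
      - {id: A1c.1, prompt: "Relationships item 1", abnormal_response: "no", precedence: investigator}
      - {id: A1c.2, prompt: "Relationships item 2", abnormal_response: "no", precedence: investigator}
      - {id: A1c.3, prompt: "Relationships item 3", abnormal_response: "no", precedence: investigator}
  - id: A2a
    label: Stereotyped movements or speech
    abnormal_min_count: 1
    questions:
      - {id: A2a.1, prompt: "Stereotypy item 1", abnormal_response: "no", precedence: investigator}
      - {id: A2a.2, prompt: "Stereotypy item 2", abnormal_response: "no", precedence: investigator}
      - {id: A2a.3, prompt: "Stereotypy item 3", abnormal_response: "no", precedence: investigator}
      - {id: A2a.4, prompt: "Stereotypy item 4", abnormal_response: "no", precedence: investigator}
      - {id: A2a.5, prompt: "Stereotypy item 5", abnormal_response: "no", precedence: investigator}
      - {id: A2a.6, prompt: "Stereotypy item 6", abnormal_response: "no", precedence: investigator}
      - {id: A2a.7, prompt: "Stereotypy item 7", abnormal_response: "no", precedence: investigator}
  - id: A2b
    label: Fixed routines
    abnormal_min_count: 1
    questions:
      - {id: A2b.1, prompt: "Fixed routines item 1", abnormal_response: "no", precedence: investigator}
  - id: A2c
    label: Fixed interests
    abnormal_min_count: 1
    questions:
      - {id: A2c.1, prompt: "Fixed interests item 1", abnormal_response: "no", precedence: investigator}
  - id: A2d
    label: Sensory symptoms
    abnormal_min_count: 1
    questions:
      - {id: A2d.1, prompt: "Sensory symptoms item 1", abnormal_response: "no", precedence: investigator}
      - {id: A2d.2, prompt: "Sensory symptoms item 2", abnormal_response: "no", precedence: investigator}
      - {id: A2d.3, prompt: "Sensory symptoms item 3", abnormal_response: "no", precedence: investigator}
      - {id: A2d.4, prompt: "Sensory symptoms item 4", abnormal_response: "no", precedence: investigator}
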