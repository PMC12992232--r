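scale:
  labels: [very unimportant, unimportant, average, important, very important]
  values: [1, 2, 3, 4, 5]
nodes:
  - {id: A, label: Effect of collaborative governance on food safety, level: 1}
  - {id: A1, label: Government regulatory capacity, level: 2, parent: A, weight: 0.3850984}
  - {id: A2, label: Implementation of corporate responsibility, level: 2, parent: A, weight: 0.11727}
  - {id: A3, label: Third parties and inspection quality, level: 2, parent: A, weight: 0.2438468}
  - {id: A4, label: Public participation, level: 2, parent: A, weight: 0.2537846}
  - {id: G1, label: Gini coefficient / urban-rural ratio of regulatory human resources and funds, level: 3, parent: A1, weight: 0.079366}
  - {id: G2, label: Coverage and targeting of supervision and sampling inspection, level: 3, parent: A1, weight: 0.031488}
  - {id: G3, label: Timeliness of responses to illegal acts and regional differences, level: 3, parent: A1, weight: 0.040207}
  - {id: G4, label: Frequency and case-type distribution of cross-departmental enforcement, level: 3, parent: A1, weight: 0.034251}
  - {id: G5, label: Transparency and understandability of regulatory information disclosure, level: 3, parent: A1, weight: 0.199787}
  - {id: E1, label: Certification rates of safety management systems by enterprise scale, level: 3, parent: A2, weight: 0.022291}
  - {id: E2, label: Enterprise-scale gradient of traceability information completeness, level: 3, parent: A2, weight: 0.020426}
  - {id: E3, label: Coverage and effectiveness of practitioner training, level: 3, parent: A2, weight: 0.024855}
  - {id: E4, label: Authenticity of self-inspection reporting and problem discovery, level: 3, parent: A2, weight: 0.025572}
  - {id: E5, label: Share of food-safety investment in revenue by industry and scale, level: 3, parent: A2, weight: 0.024126}
  - {id: T1, label: Regional equilibrium of testing-institution outlets, level: 3, parent: A3, weight: 0.026714}
  - {id: T2, label: Transparency of service charges and affordability for small enterprises, level: 3, parent: A3, weight: 0.104797}
  - {id: T3, label: Stability of test-report timeliness and commitment fulfillment, level: 3, parent: A3, weight: 0.051819}
  - {id: T4, label: Openness of proficiency-testing and flight-inspection results, level: 3, parent: A3, weight: 0.060518}
  - {id: C1, label: Group differences in risk perception and knowledge level, level: 3, parent: A4, weight: 0.063173}
  - {id: C2, label: Utilization efficiency of complaint and reporting channels, level: 3, parent: A4, weight: 0.038505}
  - {id: C3, label: Representativeness and accessibility of policy consultation, level: 3, parent: A4, weight: 0.098182}
  - {id: C4, label: Media and social-platform attention deviation, level: 3, parent: A4, weight: 0.053924}
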