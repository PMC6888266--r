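# Default indicator registry: 19 indicators in four categories.
# direction +1 means larger raw values indicate greater burden/vulnerability.
indicators:
  - id: diesel
    name: Diesel emissions
    category: environmental_exposures
    direction: 1
    source: Washington State Department of Ecology Comprehensive Emissions Inventory
    years: "2014"
    active: true
  - id: ozone
    name: Ozone
    category: environmental_exposures
    direction: 1
    source: AIRPACT
    years: "2009-2011"
    active: true
  - id: pm25
    name: PM2.5
    category: environmental_exposures
    direction: 1
    source: AIRPACT
    years: "2009-2011"
    active: true
  - id: toxic_release
    name: Toxic releases from facilities
    category: environmental_exposures
    direction: 1
    source: Risk Screening Environmental Indicators (RSEI)
    years: "2014-2016"
    active: true
  - id: traffic
    name: Traffic density
    category: environmental_exposures
    direction: 1
    source: Washington State Office of Financial Management and Washington State Department of Transportation
    years: "2017"
    active: true
  - id: lead_risk
    name: Lead risk and exposure
    category: environmental_effects
    direction: 1
    source: ACS 5 year estimates
    years: "2012-2016"
    active: true
  - id: haz_waste
    name: Proximity to hazardous waste generators and facilities
    category: environmental_effects
    direction: 1
    source: EJSCREEN
    years: "2017"
    active: true
  - id: superfund
    name: Proximity to Superfund sites
    category: environmental_effects
    direction: 1
    source: EJSCREEN
    years: "2017"
    active: true
  - id: rmp
    name: Proximity to facilities with highly toxic substances
    category: environmental_effects
    direction: 1
    source: EJSCREEN
    years: "2017"
    active: true
  - id: wastewater
    name: Wastewater discharge
    category: environmental_effects
    direction: 1
    source: EJSCREEN
    years: "2017"
    active: true
  - id: cardio
    name: Cardiovascular disease
    category: sensitive_populations
    direction: 1
    source: Washington State Department of Health Center for Health Statistics
    years: "2012-2016"
    active: true
  - id: low_birth_weight
    name: Low birth weight infants
    category: sensitive_populations
    direction: 1
    source: Washington State Department of Health Center for Health Statistics
    years: "2012-2016"
    active: true
  - id: low_education
    name: Low educational attainment
    category: socioeconomic_factors
    direction: 1
    source: ACS 5 year estimates
    years: "2012-2016"
    active: true
  - id: housing_burden
    name: Housing burden
    category: socioeconomic_factors
    direction: 1
    source: ACS 5 year estimates
    years: "2012-2016"
    active: true
  - id: ling_iso
    name: Linguistic isolation
    category: socioeconomic_factors
    direction: 1
    source: ACS 5 year estimates
    years: "2012-2016"
    active: true
  - id: poverty
    name: Poverty
    category: socioeconomic_factors
    direction: 1
    source: ACS 5 year estimates
    years: "2012-2016"
    active: true
  - id: race_eth
    name: Race (people of color)
    category: socioeconomic_factors
    direction: 1
    source: Washington State Office of Financial Management
    years: "2015"
    active: true
  - id: transport
    name: Transportation expense
    category: socioeconomic_factors
    direction: 1
    source: Center for Neighborhood Technology (CNT)
    years: "2014-2015"
    active: true
  - id: unemployment
    name: Unemployment
    category: socioeconomic_factors
    direction: 1
    source: ACS 5-year estimates
    years: "2012-2016"
    active: true
scoring:
  effects_weight: 0.5
  pb_denominator_mode: weighted_sum
  min_category_coverage: 0
  decile_bins: 10
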