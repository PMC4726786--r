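# Default property schema for time-aligned brain-behavior HDF5 files.
# Users may supply their own file with the same layout to extend or replace
# the controlled vocabulary; unknown entries downgrade to warnings, never errors.
types:
  - fMRI
  - ECoG
  - EEG
  - MEG
  - LFP
  - spikes
  - stimulus
  - physicalMovement
  - behavior
  - eyeTracking
  - audio
group_properties:
  - title
  - type
  - samplingRate
  - channelLabels
  - preprocessing
  - unit
  - description
file_header_properties:
  - experimentDescription
  - species
  - subjectId
  - subjectAge
  - subjectSex
  - experimenter
  - lab
  - recordingDate
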