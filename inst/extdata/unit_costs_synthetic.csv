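item,unit_cost_gbp,unit
surgery_episode,1800,per operated episode (admission and procedure overhead)
theatre_minute,12,per minute of theatre time
bed_day,350,per inpatient bed-day
readmission_episode,1500,per readmission episode
ae_attendance,160,per accident and emergency attendance
primary_care_visit,39,per primary-care consultation
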